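make_background <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("planted telomere tracts are recovered exactly on both strands", {
  bg <- make_background(5000, 31)
  tract <- strrep("TTTAGGG", 50)
  seq_fwd <- paste0(substr(bg, 1, 100), tract,
                    substr(bg, 101 + nchar(tract), 5000))
  tr <- find_telomere_tracts(c(pmX = seq_fwd))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$start, 101L)
  expect_equal(tr$end, 100L + 350L)
  expect_equal(tr$copies, 50L)
  expect_equal(tr$strand, "+")
  expect_true(tr$at_end)  # whole sequence shorter than the end window

  # reverse-complement copies report the minus strand
  seq_rev <- paste0(substr(bg, 1, 100), strrep("CCCTAAA", 50),
                    substr(bg, 101 + nchar(tract), 5000))
  tr2 <- find_telomere_tracts(c(pmX = seq_rev))
  expect_equal(tr2$strand, "-")
  expect_equal(tr2$copies, 50L)
})

test_that("tract chaining honors min_copies and max_gap_bp", {
  bg <- make_background(3000, 32)
  # two runs of 6 copies separated by a 10 bp spacer: merged (gap <= 21)
  piece <- paste0(strrep("TTTAGGG", 6), strrep("C", 10), strrep("TTTAGGG", 6))
  s <- paste0(substr(bg, 1, 500), piece, substr(bg, 501 + nchar(piece), 3000))
  tr <- find_telomere_tracts(c(x = s))
  expect_equal(tr$copies, 12L)
  # separated by 30 bp: two runs of 6, both below min_copies, none reported
  piece2 <- paste0(strrep("TTTAGGG", 6), strrep("C", 30), strrep("TTTAGGG", 6))
  s2 <- paste0(substr(bg, 1, 500), piece2,
               substr(bg, 501 + nchar(piece2), 3000))
  expect_equal(nrow(find_telomere_tracts(c(x = s2))), 0L)
  # no motif at all
  expect_equal(nrow(find_telomere_tracts(c(x = substr(bg, 1, 1000)))), 0L)
})

test_that("planted monomer arrays are found with copy number and period", {
  set.seed(33)
  monomer <- paste(sample(c("A", "C", "G", "T"), 496, replace = TRUE),
                   collapse = "")
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  arr <- paste(vapply(1:12, function(i) mutate(monomer, 0.01), ""),
               collapse = "")
  bg <- make_background(20000, 34)
  s <- paste0(substr(bg, 1, 4000), arr, substr(bg, 4001 + nchar(arr), 20000))
  res <- find_monomer_arrays(c(pm = s), monomer)
  expect_equal(nrow(res), 1L)
  expect_equal(res$copy_number, 12L)
  expect_equal(res$start, 4001L)
  expect_equal(res$end, 4000L + 12L * 496L)
  expect_true(abs(res$monomer_len - 496L) <= 2L)
  expect_gt(res$mean_identity, 97)

  # a single copy is below min_copies
  s1 <- paste0(substr(bg, 1, 4000), monomer, substr(bg, 4497, 20000))
  expect_equal(nrow(find_monomer_arrays(c(pm = s1), monomer)), 0L)

  expect_error(find_monomer_arrays(c(pm = s), substr(monomer, 1, 9)),
               "monomer shorter")
})

test_that("array detection is invariant under reverse complement", {
  set.seed(35)
  monomer <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = "")
  arr <- strrep(monomer, 8)
  bg <- make_background(5000, 36)
  s <- paste0(substr(bg, 1, 1000), arr, substr(bg, 1001 + nchar(arr), 5000))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- find_monomer_arrays(c(pm = s), monomer)
  rev <- find_monomer_arrays(c(pm = rc), monomer)
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$strand, "-")
  expect_equal(rev$copy_number, fwd$copy_number)
  # coordinates map to the mirrored interval
  expect_equal(nchar(s) - rev$end + 1L, fwd$start)
  expect_equal(nchar(s) - rev$start + 1L, fwd$end)
})

test_that("no two reported telomere tracts on one strand overlap", {
  bg <- make_background(10000, 37)
  s <- paste0(strrep("TTTAGGG", 15), substr(bg, 1, 2000),
              strrep("TTTAGGG", 20), substr(bg, 2001, 4000),
              strrep("CCCTAAA", 12))
  tr <- find_telomere_tracts(c(x = s))
  expect_equal(nrow(tr), 3L)
  for (st in c("+", "-")) {
    g <- tr[tr$strand == st, ]
    if (nrow(g) > 1L) {
      g <- g[order(g$start), ]
      expect_true(all(g$start[-1L] > g$end[-nrow(g)]))
    }
  }
})
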