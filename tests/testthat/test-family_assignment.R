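mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               percent_identity = as.numeric(r[[3]]),
               alignment_length = as.numeric(r[[4]]),
               mismatches = 0, gap_opens = 0, q_start = 1, q_end = 1,
               s_start = 1, s_end = 1, evalue = as.numeric(r[[5]]),
               bitscore = as.numeric(r[[6]]), stringsAsFactors = FALSE)
  }))
}

test_that("best hit per query follows bitscore, e-value, subject tie-breaks", {
  h <- mk_hits(list("g1", "ref1", 45, 400, 1e-50, 200),
               list("g1", "ref2", 80, 400, 1e-40, 150))
  expect_equal(best_hit_per_query(h)$subject_id, "ref1")
  # equal bitscores: lower e-value wins
  h2 <- mk_hits(list("g1", "refA", 45, 400, 1e-40, 200),
                list("g1", "refB", 45, 400, 1e-50, 200))
  expect_equal(best_hit_per_query(h2)$subject_id, "refB")
  # full tie: lexicographic subject
  h3 <- mk_hits(list("g1", "refB", 45, 400, 1e-50, 200),
                list("g1", "refA", 45, 400, 1e-50, 200))
  expect_equal(best_hit_per_query(h3)$subject_id, "refA")
  expect_equal(nrow(best_hit_per_query(h[0, ])), 0L)
})

test_that("candidate rule enforces inclusive boundaries", {
  hits <- mk_hits(list("ok", "r", 45.0, 400, 1e-50, 200),
                  list("short", "r", 80.0, 400, 1e-50, 200),
                  list("lowid", "r", 29.9, 400, 1e-50, 200),
                  list("edge", "r", 30.0, 400, 1e-50, 200))
  plen <- c(ok = 400L, short = 349L, lowid = 500L, edge = 350L,
            nohit = 600L)
  fa <- assign_family(plen, hits, "TPS")
  q <- setNames(fa$qualifies, fa$gene_id)
  expect_true(q[["ok"]])
  expect_false(q[["short"]])   # 349 aa rejected whatever the identity
  expect_false(q[["lowid"]])   # 29.9% rejected whatever the length
  expect_true(q[["edge"]])     # 350 aa / 30.0% accepted (boundaries inclusive)
  expect_false(q[["nohit"]])   # no hit, never a candidate
  expect_error(assign_family(plen[1:4], mk_hits(list("ghost", "r", 50, 400,
                                                     1e-10, 100)), "TPS"),
               "ghost")
})

test_that("candidate count is monotone in both thresholds and order-invariant", {
  set.seed(41)
  n <- 60
  hits <- do.call(rbind, lapply(seq_len(n), function(i) {
    mk_hits(list(sprintf("g%02d", i), "ref", runif(1, 10, 90),
                 400, 1e-30, runif(1, 50, 300)))
  }))
  plen <- setNames(sample(200:600, n, replace = TRUE),
                   sprintf("g%02d", seq_len(n)))
  count <- function(len, pid, h = hits) {
    sum(assign_family(plen, h, "F", min_peptide_len = len,
                      min_best_identity = pid)$qualifies)
  }
  for (len in c(0, 300, 400)) {
    pids <- c(0, 20, 40, 60, 100)
    expect_true(all(diff(vapply(pids, function(p) count(len, p),
                                numeric(1))) <= 0))
  }
  for (pid in c(0, 30, 60)) {
    lens <- c(0, 250, 350, 500, 700)
    expect_true(all(diff(vapply(lens, function(l) count(l, pid),
                                numeric(1))) <= 0))
  }
  # with both thresholds at zero, candidates == queries with >= 1 hit
  fa0 <- assign_family(plen, hits, "F", min_peptide_len = 0,
                       min_best_identity = 0)
  expect_setequal(fa0$gene_id[fa0$qualifies], unique(hits$query_id))
  # row order of the hit table does not matter
  shuf <- hits[sample.int(nrow(hits)), ]
  expect_equal(count(350, 30), count(350, 30, shuf))
})

test_that("domain-route assignment qualifies exactly the domain carriers", {
  pep <- c(a = 500L, b = 200L, c = 450L)
  fa <- assign_family_by_domain(pep, c("a", "b"), "CYP")
  expect_equal(fa$qualifies, c(TRUE, TRUE, FALSE))
  fa2 <- assign_family_by_domain(pep, c("a", "b"), "CYP",
                                 min_peptide_len = 300L)
  expect_equal(fa2$qualifies, c(TRUE, FALSE, FALSE))
})
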