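test_that("paralog pairing requires reciprocity and drops self-hits", {
  h <- data.frame(
    query_id = c("A", "B", "A", "A", "D", "E"),
    subject_id = c("B", "A", "C", "A", "E", "D"),
    percent_identity = 90, alignment_length = c(200, 200, 200, 200, 50, 50),
    mismatches = 0, gap_opens = 0, q_start = 1, q_end = 1, s_start = 1,
    s_end = 1, evalue = 1e-50, bitscore = 100, stringsAsFactors = FALSE)
  p <- pair_paralogs(h)
  expect_equal(p, data.frame(gene_a = "A", gene_b = "B"))  # A-C one-way,
  # A-A self, D-E below min_aln_len
  p2 <- pair_paralogs(h, min_aln_len = 10)
  expect_equal(p2$gene_a, c("A", "D"))
})

test_that("global protein alignment matches small hand-computed cases", {
  a <- align_proteins_global("MKV", "MKV")
  expect_equal(a, list(a = "MKV", b = "MKV"))
  a2 <- align_proteins_global("MKV", "MV")
  expect_equal(a2, list(a = "MKV", b = "M-V"))
  expect_error(align_proteins_global("", "M"), "empty")
  expect_error(align_proteins_global("M1K", "MK"), "non-amino-acid")
})

test_that("codon threading substitutes codons and 3-nt gaps", {
  aln <- list(a = "MKV", b = "M-V")
  th <- thread_codons(aln, "ATGAAAGTT", "ATGGTT")
  expect_equal(th, list(a = "ATGAAAGTT", b = "ATG---GTT"))
  # terminal stop codons are stripped before threading
  th2 <- thread_codons(aln, "ATGAAAGTTTGA", "ATGGTTTAA")
  expect_equal(th2, th)
  expect_error(thread_codons(aln, "ATGAAA", "ATGGTT", "gX"), "gX")
})

test_that("NG86 reproduces the hand-counted example", {
  e <- ng86_ks("TTTGCTAAA", "TTCGCTAAA")
  # per-codon synonymous sites 1/3 + 1 + 1/3 on both sequences
  expect_equal(e$S, 5 / 3, tolerance = 1e-12)
  expect_equal(e$Sd, 1)
  expect_equal(e$ps, 0.6, tolerance = 1e-12)
  expect_equal(e$ks, -0.75 * log(0.2), tolerance = 1e-12)
  expect_equal(e$ka, 0)
  expect_false(e$saturated)
  # identical sequences
  e0 <- ng86_ks("ATGGCT", "ATGGCT")
  expect_equal(e0$ks, 0)
  expect_equal(e0$ka, 0)
  # S + N == 3 x compared codons
  expect_equal(e$S + e$N, 9)
})

test_that("NG86 agrees with a literal pathway-enumeration oracle", {
  set.seed(61)
  for (i in 1:8) {
    a <- random_cds(15)
    ch <- strsplit(a, "")[[1]]
    nmut <- sample(1:8, 1)
    pos <- sample(length(ch), nmut)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    b <- paste(ch, collapse = "")
    got <- ng86_ks(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$S, want$S, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    if (!is.na(want$ks)) expect_equal(got$ks, want$ks, tolerance = 1e-9)
  }
})

test_that("NG86 is symmetric and monotone in synonymous differences", {
  set.seed(62)
  for (i in 1:10) {
    a <- random_cds(40)
    ch <- strsplit(a, "")[[1]]
    pos <- sample(length(ch), 12)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    b <- paste(ch, collapse = "")
    expect_equal(ng86_ks(a, b)$ks, ng86_ks(b, a)$ks, tolerance = 1e-12)
  }
  # adding one synonymous difference strictly increases Ks
  a <- paste(rep("GCT", 30), collapse = "")   # Ala: 3rd position fully syn
  b <- a
  prev <- ng86_ks(a, b)$ks
  for (i in 1:10) {
    substr(b, i * 3, i * 3) <- "C"            # GCT -> GCC, synonymous
    cur <- ng86_ks(a, b)$ks
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("saturation is flagged past the Jukes-Cantor domain", {
  # a single 4-fold codon pair has ps = 1: beyond the JC domain
  e <- ng86_ks("TCT", "TCG")
  expect_true(e$saturated)
  a <- paste(rep("GGG", 20), collapse = "")
  b <- paste(rep("GGA", 20), collapse = "")  # every syn site differs
  e2 <- ng86_ks(a, b)
  expect_true(e2$saturated)
  expect_true(is.na(e2$ks))
  # codons with gaps or stops are excluded from the comparison
  e3 <- ng86_ks("ATG---GCT", "ATGAAAGCT")
  expect_equal(e3$codons_compared, 2L)
  expect_error(ng86_ks("TAA", "TGA"), "no comparable codons")
})

test_that("longest-isoform selection keeps one CDS per locus", {
  seqs <- c(t1 = "ATGGCT", t2 = "ATGGCTGCT", t3 = "ATG")
  map <- c(t1 = "g1", t2 = "g1", t3 = "g2")
  sel <- select_longest_isoforms(seqs, map)
  expect_equal(sel, c(g1 = "ATGGCTGCT", g2 = "ATG"))
})

test_that("ks_for_pairs runs the full chain on mutated duplicates", {
  set.seed(63)
  cds <- c(gA = random_cds(60))
  ch <- strsplit(cds[["gA"]], "")[[1]]
  pos <- sample(length(ch), 10)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  cds[["gB"]] <- paste(ch, collapse = "")
  res <- ks_for_pairs(data.frame(gene_a = "gA", gene_b = "gB"), cds)
  expect_equal(nrow(res), 1L)
  expect_true(res$ks >= 0)
  expect_equal(res$ks, ng86_ks(cds[["gA"]], cds[["gB"]])$ks,
               tolerance = 0.15)  # alignment may shift a few codons
  expect_error(ks_for_pairs(data.frame(gene_a = "gA", gene_b = "gZ"), cds),
               "gZ")
})
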