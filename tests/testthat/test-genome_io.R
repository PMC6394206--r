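test_that("FASTA reading handles multiline records, case, and errors", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", "gt", ">b", "NNN"), f)
  s <- read_fasta(f)
  expect_identical(s, c(a = "ACGT", b = "NNN"))
  expect_identical(nchar(s), c(a = 4L, b = 3L))

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate id a")
})

test_that("FASTA round-trips through write_fasta", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(chr1 = strrep("ACGTT", 50), chr2 = "ACGTACGTACGT")
  write_fasta(seqs, f, width = 17L)
  expect_identical(read_fasta(f), seqs)
})

test_that("GFF3 loci parse with coordinate-ordered dense ranks", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t500\t900\t.\t-\t.\tID=g2",
    "chr1\tsrc\tgene\t10\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t10\t100\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t10\t50\t.\t+\t.\tParent=g1.t1",
    "chr2\tsrc\tgene\t5\t50\t.\t+\t.\tID=g3"
  ), f)
  ann <- read_gff3(f)
  # loci only, sorted by coordinate (not file order), ranks dense per seq
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$gene_id, c("g1", "g2", "g3"))
  expect_equal(ann$rank, c(0L, 1L, 0L))
  expect_equal(ann$start[ann$gene_id == "g1"], 10L)
  expect_equal(ann$strand, c("+", "-", "+"))
})

test_that("annotation construction validates coordinates and ids", {
  expect_error(genome_annotation(data.frame(
    gene_id = "g", seq_id = "c", start = 10L, end = 5L)), "end < start")
  expect_error(genome_annotation(data.frame(
    gene_id = c("g", "g"), seq_id = "c", start = 1L, end = 5L)),
    "duplicate gene_id")
  # ranks are a permutation of 0..n-1 per seq_id under shuffling
  set.seed(11)
  df <- random_annotation(60L, n_seq = 3L)
  ann <- genome_annotation(df[sample.int(nrow(df)), ])
  for (sid in unique(ann$seq_id)) {
    r <- ann$rank[ann$seq_id == sid]
    expect_identical(sort(r), seq_along(r) - 1L)
  }
})

test_that("tabular hits parse and malformed rows are rejected by line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "g1\tref1\t45.0\t400\t10\t2\t1\t400\t1\t400\t1e-50\t200",
    "g2\tref2\t88.5\t120\t3\t0\t1\t120\t5\t124\t1e-20\t90"
  ), f)
  h <- read_hits_tabular(f)
  expect_equal(nrow(h), 2L)
  expect_equal(h$percent_identity[1L], 45.0)
  expect_equal(h$bitscore[2L], 90)

  file.create(f2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_equal(nrow(read_hits_tabular(f2)), 0L)

  writeLines("g1\tref1\t45.0\t400\t10\t2\t1\t400\t1\t400\t1e-50", f)
  expect_error(read_hits_tabular(f), "line 1: expected 12 columns")
})

test_that("BED output converts 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".bed")
  iv <- data.frame(seq_id = "chr1", start = 10L, end = 100L,
                   name = "x", strand = "-")
  write_bed(iv, f)
  expect_identical(readLines(f), "chr1\t9\t100\tx\t0\t-")
  # round trip preserves coordinates exactly
  rt <- read_bed(f)
  expect_equal(rt$start, 10L)
  expect_equal(rt$end, 100L)
  expect_equal(rt$strand, "-")

  write_bed(iv[0, ], f)
  expect_identical(readLines(f), character(0))
  expect_error(write_bed(data.frame(seq_id = "c", start = 5L, end = 4L), f),
               "start > end")
})

test_that("expression tables round-trip with ids and non-negativity checks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(c(0, 1.5, 2, 0.25), 2, 2,
              dimnames = list(c("g1", "g2"), c("leaf", "root")))
  write_expression_table(m, f)
  expect_equal(read_expression_table(f), m)
  writeLines(c("gene_id\ts1", "g1\t-1"), f)
  expect_error(read_expression_table(f), "negative")
})
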