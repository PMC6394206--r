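ann_from <- function(...) {
  rows <- list(...)
  genome_annotation(do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], seq_id = r[[2]], start = r[[3]],
               end = r[[4]], stringsAsFactors = FALSE)
  })))
}

# annotation with family genes F1..F3 and background genes filling ranks
chain_fixture <- function() {
  genes <- list(list("F1", "c1", 1, 10000))
  # 6 background genes between F1 and F2
  for (i in 1:6) {
    genes[[length(genes) + 1]] <-
      list(sprintf("b%d", i), "c1", 10000 + i * 1000, 10000 + i * 1000 + 500)
  }
  genes[[length(genes) + 1]] <- list("F2", "c1", 95000, 96000)
  # 16 background genes between F2 and F3
  for (i in 1:16) {
    genes[[length(genes) + 1]] <-
      list(sprintf("c%d", i), "c1", 96000 + i * 100, 96000 + i * 100 + 50)
  }
  genes[[length(genes) + 1]] <- list("F3", "c1", 99000, 99500)
  do.call(ann_from, genes)
}

test_that("two-rule chaining joins close members and breaks on rule (1)", {
  ann <- chain_fixture()
  cl <- detect_clusters(ann, c("F1", "F2", "F3"))
  # F1-F2: 6 intervening <= 10, gap 84,999 < 100,000 -> clustered;
  # F2-F3: 16 intervening -> chain broken, F3 left a singleton
  expect_equal(cluster_partition(cl), list(c("F1", "F2")))
})

test_that("boundary cases: exactly 10 intervening clusters, gap 100 kbp does not", {
  genes <- list(list("FA", "c1", 1, 1000))
  for (i in 1:10) {
    genes[[length(genes) + 1]] <-
      list(sprintf("b%d", i), "c1", 2000 + i * 300, 2000 + i * 300 + 100)
  }
  genes[[length(genes) + 1]] <- list("FB", "c1", 50000, 51000)
  ann <- ann_from_list <- do.call(ann_from, genes)
  expect_equal(cluster_partition(detect_clusters(ann, c("FA", "FB"))),
               list(c("FA", "FB")))
  # an 11th intervening gene breaks the chain
  genes[[length(genes) + 1]] <- list("b11", "c1", 6000, 6100)
  ann11 <- do.call(ann_from, genes)
  expect_equal(nrow(detect_clusters(ann11, c("FA", "FB"))), 0L)

  # gap of exactly 100,000 bp (strict inequality) is not clustered
  gap_ann <- function(gap) {
    ann_from(list("FA", "c1", 1, 1000),
             list("FB", "c1", 1000 + gap + 1, 1000 + gap + 2000))
  }
  expect_equal(nrow(detect_clusters(gap_ann(100000L), c("FA", "FB"))), 0L)
  expect_equal(cluster_partition(detect_clusters(gap_ann(99999L),
                                                 c("FA", "FB"))),
               list(c("FA", "FB")))
})

test_that("overlapping loci have distance floored at zero and strand is ignored", {
  ann <- genome_annotation(data.frame(
    gene_id = c("FA", "FB"), seq_id = "c1",
    start = c(1000L, 1500L), end = c(2500L, 3000L),
    strand = c("+", "-")))
  cl <- detect_clusters(ann, c("FA", "FB"))
  expect_equal(nrow(cl), 2L)
})

test_that("single member or empty member sets give no clusters", {
  ann <- chain_fixture()
  expect_equal(nrow(detect_clusters(ann, "F1")), 0L)
  expect_error(detect_clusters(ann, "nope"), "unknown member")
})

test_that("detected clusters match the union-find oracle on random annotations", {
  set.seed(51)
  for (rep in 1:30) {
    df <- random_annotation(sample(30:120, 1), n_seq = 2L)
    members <- sample(df$gene_id, max(2L, rpois(1, nrow(df) / 4)))
    ann <- genome_annotation(df)
    got <- cluster_partition(detect_clusters(ann, members))
    want <- oracle_clusters(df, members)
    expect_equal(got, want)
  }
})

test_that("clusters are maximal and invariant to member/row permutations", {
  set.seed(52)
  df <- random_annotation(150L, n_seq = 2L)
  members <- sample(df$gene_id, 40L)
  ann <- genome_annotation(df)
  cl <- detect_clusters(ann, members)
  # maximality: the nearest member outside each cluster violates a rule
  fam <- ann[ann$gene_id %in% members, ]
  fam <- fam[order(fam$seq_id, fam$rank), ]
  for (cid in unique(cl$cluster_id)) {
    g <- cl[cl$cluster_id == cid, ]
    sid <- g$seq_id[1]
    f <- fam[fam$seq_id == sid, ]
    i_lo <- match(g$gene_id[which.min(g$rank)], f$gene_id)
    i_hi <- match(g$gene_id[which.max(g$rank)], f$gene_id)
    check_break <- function(i, j) {
      intervening <- f$rank[j] - f$rank[i] - 1L
      gap <- max(0L, f$start[j] - f$end[i] - 1L)
      expect_true(intervening > 10L || gap >= 100000L)
    }
    if (i_lo > 1L) check_break(i_lo - 1L, i_lo)
    if (i_hi < nrow(f)) check_break(i_hi, i_hi + 1L)
  }
  # permutation invariance (members and annotation row order)
  cl2 <- detect_clusters(genome_annotation(df[sample.int(nrow(df)), ]),
                         sample(members))
  expect_equal(cluster_partition(cl), cluster_partition(cl2))
  # accounting: member rows sum to clustered gene count
  s <- summarize_family_clustering(cl, members)
  expect_equal(s$n_clustered_genes, nrow(cl))
  expect_equal(sum(s$cluster_size_histogram *
                     as.integer(names(s$cluster_size_histogram))),
               s$n_clustered_genes)
})

test_that("co-clusters keep only mixed-family clusters", {
  genes <- list()
  pos <- 1
  for (i in 1:3) {   # alternating TPS/CYP run, all within rules
    genes[[length(genes) + 1]] <- list(sprintf("T%d", i), "c1", pos, pos + 999)
    pos <- pos + 5000
    genes[[length(genes) + 1]] <- list(sprintf("C%d", i), "c1", pos, pos + 999)
    pos <- pos + 5000
  }
  # a pure TPS pair far away
  genes[[length(genes) + 1]] <- list("T10", "c1", 5e6, 5e6 + 999)
  genes[[length(genes) + 1]] <- list("T11", "c1", 5e6 + 2000, 5e6 + 2999)
  ann <- do.call(ann_from, genes)
  cc <- co_clusters(ann, c("T1", "T2", "T3", "T10", "T11"),
                    c("C1", "C2", "C3"), "TPS", "CYP")
  expect_equal(cluster_partition(cc),
               list(sort(c(paste0("T", 1:3), paste0("C", 1:3)))))
  expect_setequal(unique(cc$family), c("TPS", "CYP"))
  # two far-apart pure clusters -> no co-cluster
  cc2 <- co_clusters(ann, c("T10", "T11"), c("C1", "C2"), "TPS", "CYP")
  expect_equal(nrow(cc2), 0L)
})

test_that("clustering summary fractions match hand counts", {
  ann <- ann_from(list("F1", "c1", 1, 100), list("F2", "c1", 500, 600),
                  list("F3", "c2", 1, 100), list("F4", "c2", 5e6, 5e6 + 99),
                  list("F5", "c3", 1, 100))
  cl <- detect_clusters(ann, paste0("F", 1:5))
  s <- summarize_family_clustering(cl, paste0("F", 1:5))
  expect_equal(s$n_clusters, 1L)
  expect_equal(s$fraction_clustered, 0.4)
  expect_equal(s$cluster_size_histogram, c("2" = 1L))
  s0 <- summarize_family_clustering(detect_clusters(ann, c("F4", "F5")),
                                    c("F4", "F5"))
  expect_equal(s0$fraction_clustered, 0)
})
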