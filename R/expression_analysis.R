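# Expression QC and classification: replicate-correlation filtering, the
# evidence-based high-confidence gene set, and expression-divergence calls
# among tandem gene copies.

#' Replicate correlation QC
#'
#' Pearson correlation on raw FPKM between each biological replicate pair; a
#' pair passes when the correlation exceeds `min_replicate_r`.
#'
#' @param table FPKM matrix (genes x samples).
#' @param replicate_pairs data.frame with columns `sample_a`, `sample_b`.
#' @param min_replicate_r Pass threshold (exclusive).
#' @return data.frame with `sample_a`, `sample_b`, `r`, `pass`.
#' @export
replicate_correlation <- function(table, replicate_pairs,
                                  min_replicate_r = 0.94) {
  if (nrow(table) < 3L) stop("need at least 3 genes")
  res <- lapply(seq_len(nrow(replicate_pairs)), function(i) {
    a <- replicate_pairs$sample_a[i]
    b <- replicate_pairs$sample_b[i]
    for (s in c(a, b)) {
      if (!s %in% colnames(table)) stop("missing sample id: ", s)
    }
    if (sd(table[, a]) == 0 || sd(table[, b]) == 0) {
      stop("zero-variance sample column: ",
           if (sd(table[, a]) == 0) a else b)
    }
    r <- cor(table[, a], table[, b])
    data.frame(sample_a = a, sample_b = b, r = r,
               pass = r > min_replicate_r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' High-confidence gene set
#'
#' A gene is included iff its FPKM exceeds 0 in any library OR it has a
#' domain (Pfam) match.  Genes absent from the table are treated as
#' all-zero.
#'
#' @param gene_ids Gene universe.
#' @param table FPKM matrix (genes x samples); may cover a subset of
#'   `gene_ids`.
#' @param pfam_hit_ids Gene ids with a domain match.
#' @return Character vector: the high-confidence subset of `gene_ids`.
#' @export
high_confidence_set <- function(gene_ids, table, pfam_hit_ids = character(0)) {
  gene_ids <- as.character(gene_ids)
  max_fpkm <- rep(0, length(gene_ids))
  idx <- match(gene_ids, rownames(table))
  hit <- !is.na(idx)
  if (any(hit)) {
    max_fpkm[hit] <- apply(table[idx[hit], , drop = FALSE], 1L, max)
  }
  gene_ids[max_fpkm > 0 | gene_ids %in% pfam_hit_ids]
}

#' Classify expression divergence within a gene cluster
#'
#' For each member: a constitutive flag (FPKM at least `expressed_fpkm` in
#' every tissue column).  For each member pair: Pearson correlation of
#' `log2(FPKM + 1)` across tissues and whether the expressed-tissue sets
#' (FPKM at least `expressed_fpkm`) are disjoint; the pair is called
#' `diverged` iff the correlation falls below `r_threshold` or the expressed
#' sets are disjoint, otherwise `conserved`.
#'
#' @param members Gene ids of the cluster (at least 2), e.g. one cluster's
#'   `gene_id` column from [detect_clusters()].
#' @param table FPKM matrix with one column per tissue (replicates already
#'   collapsed/selected).
#' @param expressed_fpkm FPKM threshold for "expressed in a tissue".
#' @param r_threshold Correlation below which a pair is called diverged.
#' @return list with `constitutive` (data.frame `gene_id`, `constitutive`)
#'   and `pairs` (data.frame `gene_a`, `gene_b`, `pearson_r`,
#'   `expressed_sets_disjoint`, `call`).
#' @export
classify_cluster_expression <- function(members, table,
                                        expressed_fpkm = 1.0,
                                        r_threshold = 0.5) {
  members <- as.character(members)
  if (length(members) < 2L) stop("cluster must have at least 2 members")
  missing_m <- setdiff(members, rownames(table))
  if (length(missing_m)) stop("gene not in expression table: ", missing_m[1L])
  m <- table[members, , drop = FALSE]
  constitutive <- data.frame(
    gene_id = members,
    constitutive = apply(m >= expressed_fpkm, 1L, all),
    stringsAsFactors = FALSE
  )
  lg <- log2(m + 1)
  expressed <- m >= expressed_fpkm
  cmb <- utils::combn(members, 2L)
  pairs <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1L, i]
    b <- cmb[2L, i]
    r <- if (sd(lg[a, ]) == 0 || sd(lg[b, ]) == 0) NA_real_ else
      cor(lg[a, ], lg[b, ])
    disjoint <- !any(expressed[a, ] & expressed[b, ])
    diverged <- isTRUE(r < r_threshold) || disjoint
    data.frame(gene_a = a, gene_b = b, pearson_r = r,
               expressed_sets_disjoint = disjoint,
               call = if (diverged) "diverged" else "conserved",
               stringsAsFactors = FALSE)
  })
  list(constitutive = constitutive, pairs = do.call(rbind, pairs))
}
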