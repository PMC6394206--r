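# Physical/tandem gene-cluster detection under the two-rule criterion:
#   (1) at most `max_intervening_genes` annotated loci between consecutive
#       family members on one pseudomolecule, and
#   (2) inter-gene distance (gap between gene spans) strictly less than
#       `max_pair_distance_bp`.
# Family members are chained in locus-rank order (single linkage); maximal
# chains of >= 2 members are clusters.

#' Detect physical (tandem) gene clusters
#'
#' Per pseudomolecule, the member genes are taken in locus-rank order and
#' consecutive members are chained iff the number of annotated loci strictly
#' between them is at most `max_intervening_genes` and the gap between their
#' spans (`start(right) - end(left) - 1`, floored at 0 for overlapping loci)
#' is strictly less than `max_pair_distance_bp`.  Maximal chains with at
#' least two members become clusters.  Strand is ignored.
#'
#' @param annotation A [genome_annotation()].
#' @param members Character vector of family gene ids (all must exist in the
#'   annotation), or a named character vector whose names are gene ids and
#'   values family labels (for mixed-family runs).
#' @param max_intervening_genes Rule (1) bound (inclusive).
#' @param max_pair_distance_bp Rule (2) bound (exclusive).
#' @param all_pairs If `TRUE`, additionally require every pair of members in
#'   a cluster (not just consecutive ones) to satisfy the distance rule;
#'   chains are split greedily at the first violation.
#' @return data.frame of class `physical_clusters`, one row per clustered
#'   gene: `cluster_id`, `seq_id`, `gene_id`, `family`, `start`, `end`,
#'   `rank`.  Zero rows when no cluster exists.
#' @export
detect_clusters <- function(annotation, members,
                            max_intervening_genes = 10L,
                            max_pair_distance_bp = 100000L,
                            all_pairs = FALSE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  fam <- if (!is.null(names(members))) {
    setNames(as.character(members), names(members))
  } else {
    setNames(rep(NA_character_, length(members)), as.character(members))
  }
  ids <- names(fam)
  unknown <- setdiff(ids, annotation$gene_id)
  if (length(unknown)) stop("unknown member gene id: ", unknown[1L])

  ann <- annotation[annotation$gene_id %in% ids, , drop = FALSE]
  ann <- ann[order(ann$seq_id, ann$rank), , drop = FALSE]
  out <- list()
  for (sid in unique(ann$seq_id)) {
    g <- ann[ann$seq_id == sid, , drop = FALSE]
    n <- nrow(g)
    if (n < 2L) next
    intervening <- g$rank[-1L] - g$rank[-n] - 1L
    gap <- pmax(0L, g$start[-1L] - g$end[-n] - 1L)
    link <- intervening <= max_intervening_genes &
      gap < max_pair_distance_bp
    grp <- cumsum(c(TRUE, !link))
    if (all_pairs) {
      # split chains further so that every within-cluster pair satisfies the
      # distance rule; greedy left-to-right
      newgrp <- integer(n)
      cur <- 1L
      first <- 1L
      newgrp[1L] <- cur
      for (i in 2L:n) {
        ok <- grp[i] == grp[i - 1L] &&
          all(pmax(0L, g$start[i] - g$end[first:(i - 1L)] - 1L) <
                max_pair_distance_bp)
        if (!ok) {
          cur <- cur + 1L
          first <- i
        }
        newgrp[i] <- cur
      }
      grp <- newgrp
    }
    sizes <- table(grp)
    keep <- grp %in% as.integer(names(sizes)[sizes >= 2L])
    if (!any(keep)) next
    g <- g[keep, , drop = FALSE]
    grp <- grp[keep]
    cid <- sprintf("%s:%02d", sid, match(grp, unique(grp)))
    out[[sid]] <- data.frame(
      cluster_id = cid, seq_id = g$seq_id, gene_id = g$gene_id,
      family = unname(fam[g$gene_id]), start = g$start, end = g$end,
      rank = g$rank, stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    cluster_id = character(0), seq_id = character(0), gene_id = character(0),
    family = character(0), start = integer(0), end = integer(0),
    rank = integer(0), stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("physical_clusters", "data.frame")
  res
}

#' Cluster spans
#'
#' One row per cluster with its genomic span and member count.
#'
#' @param clusters Result of [detect_clusters()].
#' @return data.frame with `cluster_id`, `seq_id`, `start`, `end`,
#'   `n_members`, `families` (comma-collapsed labels present, `NA`-free).
#' @export
cluster_spans <- function(clusters) {
  if (nrow(clusters) == 0L) {
    return(data.frame(cluster_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      n_members = integer(0), families = character(0),
                      stringsAsFactors = FALSE))
  }
  sp <- lapply(split(as.data.frame(clusters), clusters$cluster_id), function(g) {
    fams <- sort(unique(g$family[!is.na(g$family)]))
    data.frame(cluster_id = g$cluster_id[1L], seq_id = g$seq_id[1L],
               start = min(g$start), end = max(g$end),
               n_members = nrow(g),
               families = paste(fams, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, sp)
  rownames(res) <- NULL
  res[order(res$seq_id, res$start), , drop = FALSE]
}

#' Two-family co-clusters
#'
#' Runs [detect_clusters()] on the union of two family member sets and keeps
#' clusters containing at least one gene from each family.
#'
#' @param annotation A [genome_annotation()].
#' @param members_a,members_b Gene ids of the two families.
#' @param label_a,label_b Family labels recorded per member.
#' @inheritParams detect_clusters
#' @return `physical_clusters` data.frame restricted to mixed clusters.
#' @export
co_clusters <- function(annotation, members_a, members_b,
                        label_a = "A", label_b = "B",
                        max_intervening_genes = 10L,
                        max_pair_distance_bp = 100000L) {
  both <- intersect(members_a, members_b)
  fam <- c(setNames(rep(label_a, length(members_a)), members_a),
           setNames(rep(label_b, length(members_b)), members_b))
  fam <- fam[!duplicated(names(fam))]
  fam[both] <- paste(label_a, label_b, sep = "+")
  cl <- detect_clusters(annotation, fam,
                        max_intervening_genes = max_intervening_genes,
                        max_pair_distance_bp = max_pair_distance_bp)
  if (nrow(cl) == 0L) return(cl)
  keep_ids <- vapply(split(cl$family, cl$cluster_id), function(f) {
    any(f %in% c(label_a, paste(label_a, label_b, sep = "+"))) &&
      any(f %in% c(label_b, paste(label_a, label_b, sep = "+")))
  }, logical(1))
  res <- cl[cl$cluster_id %in% names(keep_ids)[keep_ids], , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("physical_clusters", "data.frame")
  res
}

#' Summarize family clustering
#'
#' Counts and fraction of family genes in physical clusters, plus the
#' cluster-size histogram.
#'
#' @param clusters Result of [detect_clusters()] on `members`.
#' @param members The family gene ids the clusters were detected from.
#' @return list with `n_clusters`, `n_clustered_genes`, `n_family_genes`,
#'   `fraction_clustered`, `cluster_size_histogram` (named integer vector:
#'   size -> number of clusters).
#' @export
summarize_family_clustering <- function(clusters, members) {
  members <- if (!is.null(names(members))) names(members) else members
  sizes <- if (nrow(clusters)) table(clusters$cluster_id) else integer(0)
  hist <- if (length(sizes)) table(as.integer(sizes)) else table(integer(0))
  n_fam <- length(unique(members))
  n_clustered <- length(unique(clusters$gene_id))
  list(
    n_clusters = length(sizes),
    n_clustered_genes = n_clustered,
    n_family_genes = n_fam,
    fraction_clustered = if (n_fam > 0) n_clustered / n_fam else 0,
    cluster_size_histogram = setNames(as.integer(hist), names(hist))
  )
}
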