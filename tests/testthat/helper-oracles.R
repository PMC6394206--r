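# Independent brute-force oracles and small fixture builders used across the
# suite.  These re-derive results by the most literal route available so the
# package implementations are checked against something they do not share
# code with.

# Nx by literal scan: walk the descending-sorted lengths accumulating until
# the cumulative sum reaches x% of the total.
oracle_nx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  need <- sum(as.numeric(s)) * x / 100
  acc <- 0
  for (L in s) {
    acc <- acc + L
    if (acc >= need) return(L)
  }
  stop("unreachable")
}

# Cluster detection by explicit pair graph + union-find over consecutive
# members, with intervening-gene counts recomputed from scratch by sorting
# the full annotation.
oracle_clusters <- function(ann_df, members, max_intervening = 10L,
                            max_dist = 100000L) {
  comps <- list()
  for (sid in unique(ann_df$seq_id)) {
    g <- ann_df[ann_df$seq_id == sid, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    idx <- which(g$gene_id %in% members)
    if (length(idx) < 2L) next
    parent <- seq_along(idx)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]
      j <- idx[k + 1L]
      intervening <- j - i - 1L
      gap <- max(0L, g$start[j] - g$end[i] - 1L)
      if (intervening <= max_intervening && gap < max_dist) {
        parent[find(k + 1L)] <- find(k)
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    for (r in unique(roots)) {
      mem <- g$gene_id[idx[roots == r]]
      if (length(mem) >= 2L) comps[[length(comps) + 1L]] <- sort(mem)
    }
  }
  # canonical form: sorted list of sorted member sets
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

# canonical member-set partition of a detect_clusters() result
cluster_partition <- function(cl) {
  if (nrow(cl) == 0L) return(list())
  sets <- lapply(split(cl$gene_id, cl$cluster_id), sort)
  names(sets) <- NULL
  sets[order(vapply(sets, `[`, character(1), 1L))]
}

# random annotation: n genes over n_seq sequences, non-overlapping-ish
# intervals with geometric-ish gaps so both cluster rules get exercised
random_annotation <- function(n, n_seq = 2L, max_gap = 60000L) {
  seq_id <- sort(sample(sprintf("s%d", seq_len(n_seq)), n, replace = TRUE))
  df <- do.call(rbind, lapply(split(seq_along(seq_id), seq_id), function(i) {
    k <- length(i)
    len <- sample(200:3000, k, replace = TRUE)
    gap <- sample(0:max_gap, k, replace = TRUE)
    start <- cumsum(gap + c(0L, len[-k])) + 1L
    data.frame(gene_id = sprintf("%s_g%03d", seq_id[i[1L]], seq_len(k)),
               seq_id = seq_id[i[1L]], start = start,
               end = start + len - 1L, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

# slow literal NG86 for short sequences: per-codon site fractions and
# pathway-averaged differences computed with string operations only
oracle_ng86 <- function(a, b) {
  gcode <- Biostrings::GENETIC_CODE
  translate1 <- function(cod) unname(gcode[[cod]])
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(cod) {
    s <- 0
    for (p in 1:3) {
      for (nb in setdiff(bases, substr(cod, p, p))) {
        mut <- cod
        substr(mut, p, p) <- nb
        if (translate1(mut) == translate1(cod)) s <- s + 1 / 3
      }
    }
    s
  }
  path_diffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(pos) == 0) return(c(0, 0))
    all_orders <- if (length(pos) == 1) list(pos) else {
      do.call(c, lapply(seq_along(pos), function(i) {
        lapply(if (length(pos) == 2) list(pos[-i]) else {
          list(pos[-i], rev(pos[-i]))
        }, function(rest) c(pos[i], rest))
      }))
    }
    acc <- NULL
    for (ord in all_orders) {
      cur <- c1
      s <- 0
      n <- 0
      ok <- TRUE
      for (step in seq_along(ord)) {
        nxt <- cur
        substr(nxt, ord[step], ord[step]) <-
          substr(c2, ord[step], ord[step])
        if (translate1(nxt) == "*" && step < length(ord)) {
          ok <- FALSE
          break
        }
        if (translate1(cur) == translate1(nxt)) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (ok) acc <- rbind(acc, c(s, n))
    }
    colMeans(acc)
  }
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  vt <- Vectorize(translate1)
  keep <- vt(ca) != "*" & vt(cb) != "*"
  ca <- ca[keep]
  cb <- cb[keep]
  S <- (sum(vapply(ca, syn_sites, 1)) + sum(vapply(cb, syn_sites, 1))) / 2
  d <- rowSums(vapply(seq_along(ca), function(i) path_diffs(ca[i], cb[i]),
                      numeric(2)))
  ps <- d[1] / S
  list(S = S, Sd = d[1], Nd = d[2], ps = ps,
       ks = if (4 / 3 * ps < 1) -3 / 4 * log(1 - 4 / 3 * ps) else NA_real_)
}

# random stop-free CDS of n codons
random_cds <- function(n_codons) {
  gcode <- Biostrings::GENETIC_CODE
  cods <- names(gcode)[gcode != "*"]
  paste(sample(cods, n_codons, replace = TRUE), collapse = "")
}
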