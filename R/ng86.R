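# Nei-Gojobori (1986) synonymous/nonsynonymous site and difference counting
# with Jukes-Cantor correction.  Per-codon site fractions and pairwise
# difference counts (averaged over all minimal substitution pathways that do
# not pass through a stop codon) are precomputed once into 64-wide lookup
# tables, so per-pair estimation is a handful of vectorized lookups.

.ng_cache <- new.env(parent = emptyenv())

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' NG86 codon lookup tables
#'
#' Builds (once per session) the standard-genetic-code lookup tables used by
#' [ng86_ks()]: per-codon synonymous site counts (changes to stop codons
#' count as nonsynonymous) and 64x64 pairwise synonymous/nonsynonymous
#' difference counts averaged over all minimal substitution pathways, with
#' pathways through stop codons excluded (if every pathway is blocked, all
#' pathways are used).
#'
#' @return list with `codons` (64 codon strings), `aa`, `syn` (per-codon
#'   synonymous sites; `NA` for stops), `Sd`, `Nd` (64x64 matrices), and
#'   `mut_*` proposal tables used by the sequence simulator.
#' @export
ng86_tables <- function() {
  if (!is.null(.ng_cache$tab)) return(.ng_cache$tab)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  bases <- c("A", "C", "G", "T")
  cod_mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))

  syn <- rep(NA_real_, 64L)
  # mutation proposal tables: 9 single-base changes per codon
  mut_new <- matrix(NA_integer_, 64L, 9L)
  mut_syn <- matrix(FALSE, 64L, 9L)
  mut_stop <- matrix(FALSE, 64L, 9L)
  for (i in seq_len(64L)) {
    k <- 0L
    nsyn <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, cod_mat[i, p])) {
        k <- k + 1L
        mut <- cod_mat[i, ]
        mut[p] <- b
        j <- match(paste(mut, collapse = ""), codons)
        mut_new[i, k] <- j
        mut_stop[i, k] <- aa[j] == "*"
        mut_syn[i, k] <- aa[j] == aa[i] && aa[i] != "*"
        if (aa[i] != "*" && aa[j] == aa[i]) nsyn <- nsyn + 1
      }
    }
    if (aa[i] != "*") syn[i] <- nsyn / 3
  }

  Sd <- matrix(NA_real_, 64L, 64L)
  Nd <- matrix(NA_real_, 64L, 64L)
  for (i in seq_len(64L)) {
    if (aa[i] == "*") next
    for (j in i:64L) {
      if (aa[j] == "*") next
      diffpos <- which(cod_mat[i, ] != cod_mat[j, ])
      if (length(diffpos) == 0L) {
        Sd[i, j] <- Nd[i, j] <- 0
        next
      }
      path_counts <- function(exclude_stops) {
        res <- NULL
        for (path in perms_of(diffpos)) {
          cur <- cod_mat[i, ]
          s <- 0
          n <- 0
          ok <- TRUE
          for (step in seq_along(path)) {
            nxt <- cur
            nxt[path[step]] <- cod_mat[j, path[step]]
            ci <- match(paste(cur, collapse = ""), codons)
            cj <- match(paste(nxt, collapse = ""), codons)
            if (exclude_stops && aa[cj] == "*" && step < length(path)) {
              ok <- FALSE
              break
            }
            if (aa[ci] == aa[cj]) s <- s + 1 else n <- n + 1
            cur <- nxt
          }
          if (ok) res <- rbind(res, c(s, n))
        }
        res
      }
      pc <- path_counts(TRUE)
      if (is.null(pc)) pc <- path_counts(FALSE)
      Sd[i, j] <- Sd[j, i] <- mean(pc[, 1L])
      Nd[i, j] <- Nd[j, i] <- mean(pc[, 2L])
    }
  }
  .ng_cache$tab <- list(codons = codons, aa = aa, syn = syn, Sd = Sd,
                        Nd = Nd, mut_new = mut_new, mut_syn = mut_syn,
                        mut_stop = mut_stop)
  .ng_cache$tab
}

# split an aligned CDS string into codon strings
codon_split <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("alignment length not divisible by 3")
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# NG86 on codon-index vectors (1..64); codons with NA index (gap/ambiguous)
# or stop in either sequence are skipped
ng86_core <- function(ia, ib, tab = ng86_tables()) {
  keep <- !is.na(ia) & !is.na(ib) & !is.na(tab$syn[ia]) & !is.na(tab$syn[ib])
  ia <- ia[keep]
  ib <- ib[keep]
  ncod <- length(ia)
  if (ncod == 0L) stop("no comparable codons")
  S <- (sum(tab$syn[ia]) + sum(tab$syn[ib])) / 2
  N <- 3 * ncod - S
  Sd <- sum(tab$Sd[cbind(ia, ib)])
  Nd <- sum(tab$Nd[cbind(ia, ib)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  saturated <- (4 / 3 * ps >= 1) || (4 / 3 * pn >= 1)
  ks <- if (4 / 3 * ps < 1) -3 / 4 * log(1 - 4 / 3 * ps) else NA_real_
  ka <- if (4 / 3 * pn < 1) -3 / 4 * log(1 - 4 / 3 * pn) else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 ks = ks, ka = ka, saturated = saturated,
                 codons_compared = ncod),
            class = "ks_estimate")
}

#' Nei-Gojobori Ks/Ka estimate for an aligned CDS pair
#'
#' Synonymous and nonsynonymous sites are counted as the average over both
#' sequences of per-codon synonymous site fractions; differences in codons
#' with multiple changes are averaged over all minimal substitution pathways
#' excluding stop-codon intermediates.  Proportions are Jukes-Cantor
#' corrected: `ks = -3/4 log(1 - 4/3 ps)`; when `4/3 ps >= 1` (or the same
#' for `pn`) the estimate is flagged saturated.  Codons containing gaps,
#' ambiguous bases, or a stop in either sequence are skipped.
#'
#' @param cds_a,cds_b Aligned coding sequences of equal length divisible by
#'   3 (gaps as `-`, threaded in whole codons), or unaligned equal-length
#'   gap-free CDS.
#' @return `ks_estimate` list: `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `ks`, `ka`,
#'   `saturated`, `codons_compared`.
#' @examples
#' ng86_ks("TTTGCTAAA", "TTCGCTAAA")$ks  # 1.2071
#' @export
ng86_ks <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a)
  cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("aligned sequences must have equal length")
  }
  tab <- ng86_tables()
  ca <- codon_split(cds_a)
  cb <- codon_split(cds_b)
  ng86_core(match(ca, tab$codons), match(cb, tab$codons), tab)
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf(
    "NG86 estimate over %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
    x$codons_compared, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  ps=%.4f pn=%.4f Ks=%s Ka=%s%s\n", x$ps, x$pn,
              format(round(x$ks, 4)), format(round(x$ka, 4)),
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}
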