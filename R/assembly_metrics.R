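#' Nx contiguity statistic
#'
#' Length of the sequence at which the cumulative sum of lengths, sorted in
#' descending order, first reaches at least `x` percent of the assembly
#' total (N50 at `x = 50`, N90 at `x = 90`).
#'
#' @param lengths Integer vector of sequence lengths, all positive.
#' @param x Percentage in (0, 100].
#' @return The Nx length.
#' @export
nx <- function(lengths, x = 50) {
  if (length(lengths) == 0L) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  i <- which(cumsum(s) >= sum(s) * (x / 100))[1L]
  s[i]
}

#' Assembly contiguity summary
#'
#' Standard whole-assembly statistics: sequence count, total/max/min size,
#' N50, N90, and mean size (reported as an integer, rounded half-up).
#'
#' @param lengths Integer vector of sequence lengths.
#' @return list of class `assembly_summary` with fields `n_sequences`,
#'   `total_bp`, `max_bp`, `min_bp`, `n50_bp`, `n90_bp`, `mean_bp`.
#' @export
assembly_summary <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  lengths <- as.numeric(lengths)
  out <- list(
    n_sequences = length(lengths),
    total_bp = sum(lengths),
    max_bp = max(lengths),
    min_bp = min(lengths),
    n50_bp = nx(lengths, 50),
    n90_bp = nx(lengths, 90),
    mean_bp = floor(sum(lengths) / length(lengths) + 0.5)
  )
  class(out) <- "assembly_summary"
  out
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat("Assembly summary\n")
  for (f in names(unclass(x))) {
    cat(sprintf("  %-12s %s\n", f,
                format(x[[f]], big.mark = ",", scientific = FALSE)))
  }
  invisible(x)
}

#' Cumulative size-class table
#'
#' For each size threshold, the total length, percent of the assembly
#' (rounded to 2 decimals), and count of sequences at least that long.
#'
#' @param lengths Integer vector of sequence lengths.
#' @param thresholds Strictly decreasing size thresholds in bp.
#' @return data.frame with `threshold_bp`, `total_bp`, `pct_assembly`,
#'   `count`.
#' @export
size_class_table <- function(lengths,
                             thresholds = c(1e6, 5e5, 1e5, 5e4)) {
  if (length(lengths) == 0L) stop("empty length list")
  if (any(diff(thresholds) >= 0)) stop("thresholds must be strictly decreasing")
  lengths <- as.numeric(lengths)
  total <- sum(lengths)
  rows <- lapply(thresholds, function(t) {
    sel <- lengths >= t
    data.frame(threshold_bp = t,
               total_bp = sum(lengths[sel]),
               pct_assembly = round(100 * sum(lengths[sel]) / total, 2),
               count = sum(sel))
  })
  do.call(rbind, rows)
}
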