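# SiZer ("SIgnificant ZERo crossings of derivatives", Chaudhuri & Marron
# 1999): a scale-space map classifying, for a grid of locations x and
# bandwidths h, whether the Gaussian-kernel density estimate's slope is
# significantly increasing, decreasing, or flat.  Simultaneous confidence
# intervals use the independent-blocks quantile; grid cells with effective
# sample size below 5 are marked sparse.

#' SiZer scale-space map
#'
#' For every (x, h) cell: the kernel density-derivative estimate
#' `f'(x) = mean_i Kh'(x - Xi)` with its estimated standard error, a
#' row-wise simultaneous quantile `q(h)` from the independent-blocks
#' approximation (`m(h)` blocks of width `2h` across the data range), and a
#' state: `"increase"` if the CI is entirely above 0, `"decrease"` if
#' entirely below, `"flat"` otherwise, `"sparse"` where the effective sample
#' size `ESS(x,h) = sum_i Kh(x - Xi) / Kh(0)` is below 5.
#'
#' @param values Numeric sample (>= 20 non-degenerate values).
#' @param x_grid Evaluation grid; default 101 equally spaced points spanning
#'   the data.
#' @param h_grid Bandwidth grid; default 11 log-spaced bandwidths spanning
#'   1/5x to 5x the normal-reference bandwidth.
#' @param alpha Simultaneous significance level per bandwidth row.
#' @return `sizer_map` list: `x_grid`, `h_grid`, `state` (h x x character
#'   matrix), `deriv`, `se`, `ess`, `q`, `alpha`.
#' @export
sizer <- function(values, x_grid = NULL, h_grid = NULL, alpha = 0.05) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 20L) stop("need at least 20 values")
  if (sd(x) == 0) stop("degenerate (zero-variance) data")
  if (is.null(x_grid)) {
    x_grid <- seq(min(x), max(x), length.out = 101L)
  }
  if (is.null(h_grid)) {
    h0 <- stats::bw.nrd0(x)
    h_grid <- exp(seq(log(h0 / 5), log(h0 * 5), length.out = 11L))
  }
  nh <- length(h_grid)
  ngx <- length(x_grid)
  state <- matrix("flat", nh, ngx)
  deriv <- se <- ess <- matrix(NA_real_, nh, ngx)
  qs <- numeric(nh)
  rng <- diff(range(x))
  for (hi in seq_len(nh)) {
    h <- h_grid[hi]
    u <- outer(x_grid, x, "-")              # ngx x n
    phi <- dnorm(u / h)
    kh <- phi / h
    khd <- -(u / h^2) * phi / h             # d/dx of Kh(x - Xi)
    deriv[hi, ] <- rowMeans(khd)
    v <- rowMeans(khd^2) - rowMeans(khd)^2  # per-cell variance of Kh'
    se[hi, ] <- sqrt(pmax(v, 0) / n)
    ess[hi, ] <- rowSums(kh) * h / dnorm(0)
    m <- max(1, rng / (2 * h))
    q <- qnorm((1 + (1 - alpha)^(1 / m)) / 2)
    qs[hi] <- q
    lo <- deriv[hi, ] - q * se[hi, ]
    hi_ci <- deriv[hi, ] + q * se[hi, ]
    st <- rep("flat", ngx)
    st[lo > 0] <- "increase"
    st[hi_ci < 0] <- "decrease"
    st[ess[hi, ] < 5] <- "sparse"
    state[hi, ] <- st
  }
  structure(list(x_grid = x_grid, h_grid = h_grid, state = state,
                 deriv = deriv, se = se, ess = ess, q = qs, alpha = alpha),
            class = "sizer_map")
}

# modes in one row of states: an increase run whose next non-flat state
# (sparse breaks the scan) is a decrease run; returns data.frame of
# x-intervals (between last increase and first decrease column)
row_modes <- function(states, x_grid) {
  out <- NULL
  i <- 1L
  ngx <- length(states)
  while (i <= ngx) {
    if (states[i] == "increase") {
      # end of this increase run
      j <- i
      while (j < ngx && states[j + 1L] == "increase") j <- j + 1L
      # scan forward over flats for a decrease
      k <- j + 1L
      while (k <= ngx && states[k] == "flat") k <- k + 1L
      if (k <= ngx && states[k] == "decrease") {
        out <- rbind(out, data.frame(x_lo = x_grid[j], x_hi = x_grid[k]))
        while (k < ngx && states[k + 1L] == "decrease") k <- k + 1L
        i <- k + 1L
      } else {
        i <- k
      }
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) data.frame(x_lo = numeric(0), x_hi = numeric(0)) else out
}

#' Significant modes from a SiZer map
#'
#' A mode is an x-location where, over a contiguous range of bandwidths, a
#' significant increase region is followed (in x) by a significant decrease
#' region.  Per-row modes are grouped across adjacent bandwidths when their
#' x-intervals overlap.
#'
#' @param map A `sizer_map`.
#' @return data.frame with one row per mode: `x_lo`, `x_hi` (x-interval at
#'   the smallest supporting bandwidth), `h_lo`, `h_hi`, `n_bandwidths`.
#' @export
significant_modes <- function(map) {
  per_row <- lapply(seq_along(map$h_grid), function(hi) {
    m <- row_modes(map$state[hi, ], map$x_grid)
    if (nrow(m)) m$h <- map$h_grid[hi]
    m
  })
  rows <- do.call(rbind, per_row[vapply(per_row, nrow, integer(1)) > 0])
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(x_lo = numeric(0), x_hi = numeric(0),
                      h_lo = numeric(0), h_hi = numeric(0),
                      n_bandwidths = integer(0)))
  }
  rows <- rows[order(rows$h, rows$x_lo), , drop = FALSE]
  groups <- list()
  for (i in seq_len(nrow(rows))) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      # same mode: x-intervals overlap and bandwidth adjacent in the grid
      if (rows$x_lo[i] <= max(g$x_hi) && rows$x_hi[i] >= min(g$x_lo)) {
        groups[[gi]] <- rbind(g, rows[i, ])
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- rows[i, ]
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    g0 <- g[which.min(g$h), ]
    data.frame(x_lo = g0$x_lo, x_hi = g0$x_hi,
               h_lo = min(g$h), h_hi = max(g$h),
               n_bandwidths = nrow(g))
  }))
  out[order(out$x_lo), , drop = FALSE]
}

#' Modes visible at one bandwidth
#'
#' @param map A `sizer_map`.
#' @param h Bandwidth; the nearest grid row is used.
#' @return data.frame of mode x-intervals in that row.
#' @export
modes_at_bandwidth <- function(map, h) {
  hi <- which.min(abs(map$h_grid - h))
  row_modes(map$state[hi, ], map$x_grid)
}

#' @export
print.sizer_map <- function(x, ...) {
  cat(sprintf("SiZer map: %d x-points, %d bandwidths (alpha=%g)\n",
              length(x$x_grid), length(x$h_grid), x$alpha))
  tab <- table(factor(x$state, c("increase", "decrease", "flat", "sparse")))
  cat("  cell states:", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Plot a SiZer map
#'
#' Blue = significant increase, red = significant decrease, purple = no
#' significant change, grey = sparse data; the y-axis is log10 bandwidth.
#'
#' @param x A `sizer_map`.
#' @param ... Ignored.
#' @export
plot.sizer_map <- function(x, ...) {
  codes <- matrix(match(x$state, c("increase", "decrease", "flat", "sparse")),
                  nrow(x$state), ncol(x$state))
  graphics::image(x$x_grid, log10(x$h_grid), t(codes), zlim = c(1, 4),
                  col = c("#2c4fbe", "#c03a2b", "#8e6bb2", "#bdbdbd"),
                  xlab = "Ks", ylab = "log10 bandwidth", main = "SiZer map")
  invisible(x)
}

#' Write a SiZer map as a long-format TSV
#'
#' @param map A `sizer_map`.
#' @param path Output path.
#' @export
write_sizer_tsv <- function(map, path) {
  df <- expand.grid(h = map$h_grid, x = map$x_grid,
                    KEEP.OUT.ATTRS = FALSE)
  df$state <- as.vector(map$state)
  df <- df[, c("x", "h", "state")]
  write.table(df[order(df$h, df$x), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
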