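#' Hartigan's dip statistic and test of unimodality
#'
#' The dip of an empirical CDF Fn is the smallest sup-norm distance between
#' Fn and any unimodal CDF. It is computed here from the classic greatest
#' convex minorant / least concave majorant (GCM/LCM) characterization: the
#' GCM is the lower convex hull of the points (x_(i), (i-1)/n), the LCM the
#' upper concave hull of (x_(i), i/n); the algorithm repeatedly finds the
#' largest GCM-LCM gap, shrinks the candidate modal interval to it, and
#' accumulates the deviation of Fn outside the modal interval. Half the
#' largest irreducible deviation is the dip. For any sample the dip is at
#' least 1/(2n); a balanced two-point sample attains the maximal value 1/4.
#'
#' @name dip
NULL

# Lower convex hull indices of points (x[i], y[i]), x non-decreasing.
.lower_hull <- function(x, y) {
  n <- length(x)
  h <- integer(n); m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      # pop while the new point makes the last hull point non-convex
      cr <- (x[h[m]] - x[h[m - 1L]]) * (y[i] - y[h[m - 1L]]) -
        (y[h[m]] - y[h[m - 1L]]) * (x[i] - x[h[m - 1L]])
      if (cr < 0) m <- m - 1L else break
    }
    m <- m + 1L; h[m] <- i
  }
  h[seq_len(m)]
}

# Piecewise-linear interpolation of a hull through (x[h], y[h]) at all x.
.hull_eval <- function(x, y, h) {
  if (length(h) == 1L) return(rep(y[h], length(x)))
  stats::approx(x[h], y[h], xout = x, rule = 2, ties = "ordered")$y
}

#' Dip statistic
#'
#' @param samples numeric vector, `n >= 2` (a constant sample returns the
#'   boundary value `1/(2n)`).
#' @return the dip statistic, in `[1/(2n), 1/4]`.
#' @export
dip_statistic <- function(samples) {
  x0 <- sort(as.numeric(samples))
  n <- length(x0)
  if (n < 2L) stop("need at least 2 observations")
  ux <- unique(x0)
  if (length(ux) == 1L) return(1 / (2 * n))
  cnt <- as.numeric(table(factor(x0, levels = ux)))
  Fhi <- cumsum(cnt) / n        # Fn at each unique point (right limit)
  Flo <- c(0, Fhi[-length(Fhi)])  # left limit
  m <- length(ux)

  lo <- 1L; hi <- m
  best <- 0
  repeat {
    xs <- ux[lo:hi]
    ylo <- Flo[lo:hi]; yhi <- Fhi[lo:hi]
    g <- .lower_hull(xs, ylo)                # GCM touches lower corners
    l <- .lower_hull(xs, -yhi)               # LCM = upper hull of upper corners
    gcm_at <- .hull_eval(xs, ylo, g)
    lcm_at <- -.hull_eval(xs, -yhi, l)
    # largest gap between the two curves, evaluated at all window points
    gap <- lcm_at - gcm_at
    d <- max(gap)
    if (d <= best + 1e-15) break
    j <- which.max(gap)
    # modal interval: GCM touch point at/left of j .. LCM touch point at/right
    ml <- max(g[g <= j]); mh <- min(l[l >= j])
    # deviations of Fn outside the modal interval w.r.t. the current hulls
    dl <- if (ml > 1L) max(yhi[1:ml] - gcm_at[1:ml]) else 0
    du <- if (mh < length(xs)) max(lcm_at[mh:length(xs)] - ylo[mh:length(xs)]) else 0
    best <- max(best, dl, du)
    if (ml == 1L && mh == length(xs)) { best <- max(best, d); break }
    lo2 <- lo + ml - 1L; hi2 <- lo + mh - 1L
    if (lo2 == lo && hi2 == hi) { best <- max(best, d); break }
    lo <- lo2; hi <- hi2
  }
  max(best / 2, 1 / (2 * n))
}

# Bootstrap reference tables are cached per (n, n_boot, seed): the null
# distribution of the dip is conventionally calibrated on Uniform(0,1)
# samples of the same size.
.dip_cache <- new.env(parent = emptyenv())

#' Dip test of unimodality
#'
#' Bootstrap p-value: `n_boot` Uniform(0,1) reference samples of the same
#' size are drawn under `seed`, and the p-value is the (add-one) fraction of
#' reference dips at least as large as the observed dip.
#'
#' @param samples numeric vector, `n >= 10` recommended (constant samples get
#'   `p = 1`).
#' @param n_boot number of bootstrap reference samples.
#' @param seed integer seed for the reference draws (results are
#'   deterministic given `seed`).
#' @return list with `dip_statistic` and `p_value`.
#' @export
dip_test <- function(samples, n_boot = 200L, seed = 1L) {
  n <- length(samples)
  d <- dip_statistic(samples)
  if (length(unique(samples)) == 1L)
    return(list(dip_statistic = d, p_value = 1))
  key <- sprintf("n%d_b%d_s%d", n, n_boot, as.integer(seed))
  if (is.null(.dip_cache[[key]])) {
    set.seed(as.integer(seed))
    .dip_cache[[key]] <- vapply(seq_len(n_boot),
                                function(i) dip_statistic(stats::runif(n)),
                                numeric(1))
  }
  ref <- .dip_cache[[key]]
  list(dip_statistic = d,
       p_value = (1 + sum(ref >= d)) / (n_boot + 1))
}
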