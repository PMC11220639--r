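#' Configuration for unbiased step fitting of efficiency traces
#'
#' @param max_steps maximum number of change points to place.
#' @param min_plateau_length minimum plateau length in frames (>= 2).
#' @param quality_threshold minimum fit/counter-fit chi-square ratio at
#'   the selected step count; below it the trace is declared step-free.
#' @param merge_tolerance adjacent plateaus whose means differ by less
#'   than this (efficiency units) are merged after fitting.
#' @return A list of class `step_fit_config`.
#' @export
step_fit_config <- function(max_steps = 40L,
                            min_plateau_length = 5L,
                            quality_threshold = 1.25,
                            merge_tolerance = 0.08) {
  if (min_plateau_length < 2) stop("`min_plateau_length` must be >= 2",
                                   call. = FALSE)
  if (max_steps < 0) stop("`max_steps` must be >= 0", call. = FALSE)
  structure(list(max_steps = as.integer(max_steps),
                 min_plateau_length = as.integer(min_plateau_length),
                 quality_threshold = quality_threshold,
                 merge_tolerance = merge_tolerance),
            class = "step_fit_config")
}

# Residual sum of squares of segment [i, j] (1-based inclusive) from
# prefix sums s1, s2 (length n + 1, s[k+1] = sum of first k values).
seg_rss <- function(s1, s2, i, j) {
  len <- j - i + 1
  (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / len
}

# Best admissible split of plateau [i, j]: both children >= mpl frames.
# Returns c(gain, split) where split is the last index of the left
# child, or c(-Inf, NA) when no admissible split exists.
best_split <- function(s1, s2, i, j, mpl) {
  lo <- i + mpl - 1L
  hi <- j - mpl
  if (hi < lo) return(c(-Inf, NA_real_))
  t <- lo:hi
  left_len <- t - i + 1
  right_len <- j - t
  left_sum <- s1[t + 1] - s1[i]
  right_sum <- s1[j + 1] - s1[t + 1]
  rss_split <- (s2[j + 1] - s2[i]) -
    left_sum^2 / left_len - right_sum^2 / right_len
  k <- which.min(rss_split)
  gain <- seg_rss(s1, s2, i, j) - rss_split[k]
  c(gain, t[k])
}

# RSS of the segmentation given interior boundaries (values are last
# indices of each segment, 1-based, strictly increasing, < n).
segmentation_rss <- function(s1, s2, bounds, n) {
  ends <- c(bounds, n)
  starts <- c(1L, bounds + 1L)
  sum(vapply(seq_along(ends), function(q) {
    seg_rss(s1, s2, starts[q], ends[q])
  }, numeric(1)))
}

# Counter-fit boundaries: a step at the midpoint of every plateau of
# the current fit that is at least 2 frames long.
counter_bounds <- function(bounds, n) {
  ends <- c(bounds, n)
  starts <- c(1L, bounds + 1L)
  mids <- floor((starts + ends) / 2)
  mids <- mids[mids >= 1L & mids < n & (ends - starts) >= 1L]
  sort(unique(mids))
}

#' Idealize an efficiency trace as a piecewise-constant step fit
#'
#' Iterative top-down step finding: at each iteration the single new
#' change point that maximally reduces the residual sum of squares is
#' placed, searching exhaustively over all admissible split points of
#' all current plateaus. After each addition the counter-fit (steps
#' moved to the midpoints of the current plateaus) chi-square is
#' computed; the retained step count maximizes the counter-fit/fit
#' chi-square quality ratio, subject to `quality_threshold` and
#' `max_steps`. Adjacent plateaus closer than `merge_tolerance` in mean
#' are merged afterwards, so pure-noise wiggles do not masquerade as
#' conformational states.
#'
#' @param trace an `efficiency_trace` (or bare numeric vector of
#'   efficiencies). `NA` frames are bridged by linear interpolation.
#' @param cfg a [step_fit_config()].
#' @return A list of class `step_fit` with `plateaus` (data.frame
#'   `start`, `end`, `mean`; frame indices 0-based, `end` exclusive,
#'   tiling the whole trace), `rss`, `n_steps`, and `quality` (the
#'   fit-quality curve per explored step count).
#' @examples
#' y <- c(rep(0.27, 100), rep(0.67, 100))
#' f <- fit_steps(y)
#' f$plateaus
#' @export
fit_steps <- function(trace, cfg = step_fit_config()) {
  y <- if (inherits(trace, "efficiency_trace")) trace$efficiency
       else as.numeric(trace)
  if (!inherits(cfg, "step_fit_config")) {
    stop("`cfg` must come from step_fit_config()", call. = FALSE)
  }
  n <- length(y)
  mpl <- cfg$min_plateau_length
  if (n < 2L * mpl) {
    stop(sprintf("trace too short for step fitting (%d < %d frames)",
                 n, 2L * mpl), call. = FALSE)
  }
  if (anyNA(y)) {
    ok <- which(!is.na(y))
    if (length(ok) < 2L) stop("trace has fewer than 2 usable frames",
                              call. = FALSE)
    y <- stats::approx(ok, y[ok], xout = seq_len(n), rule = 2)$y
  }
  s1 <- c(0, cumsum(y))
  s2 <- c(0, cumsum(y^2))
  eps <- 1e-10 * (s2[n + 1] - s1[n + 1]^2 / n + 1)

  bounds <- integer(0)               # interior boundaries (left-child ends)
  # cached best split per plateau, keyed by plateau start index
  splits <- list()
  splits[["1"]] <- best_split(s1, s2, 1L, n, mpl)
  history <- vector("list", cfg$max_steps)
  fit_rss <- numeric(0)
  quality <- numeric(0)

  k <- 0L
  while (k < cfg$max_steps) {
    starts <- c(1L, bounds + 1L)
    gains <- vapply(as.character(starts), function(s) splits[[s]][1],
                    numeric(1))
    best <- which.max(gains)
    if (!is.finite(gains[best]) || gains[best] <= eps) break
    i <- starts[best]
    j <- c(bounds, n)[best]
    t <- as.integer(splits[[as.character(i)]][2])
    bounds <- sort(c(bounds, t))
    splits[[as.character(i)]] <- best_split(s1, s2, i, t, mpl)
    splits[[as.character(t + 1L)]] <- best_split(s1, s2, t + 1L, j, mpl)
    k <- k + 1L
    history[[k]] <- bounds
    fit_rss[k] <- segmentation_rss(s1, s2, bounds, n)
    cb <- counter_bounds(bounds, n)
    counter_rss <- segmentation_rss(s1, s2, cb, n)
    quality[k] <- if (fit_rss[k] <= eps) Inf else counter_rss / fit_rss[k]
  }

  if (k > 0L && max(quality) >= cfg$quality_threshold) {
    k_star <- which.max(quality)
    bounds <- history[[k_star]]
  } else {
    k_star <- 0L
    bounds <- integer(0)
  }

  # merge adjacent plateaus with nearly equal means
  repeat {
    ends <- c(bounds, n)
    starts <- c(1L, bounds + 1L)
    means <- (s1[ends + 1] - s1[starts]) / (ends - starts + 1)
    if (length(means) < 2L) break
    dm <- abs(diff(means))
    w <- which(dm < cfg$merge_tolerance)
    if (length(w) == 0L) break
    drop <- w[which.min(dm[w])]
    bounds <- bounds[-drop]
  }
  ends <- c(bounds, n)
  starts <- c(1L, bounds + 1L)
  means <- (s1[ends + 1] - s1[starts]) / (ends - starts + 1)
  plateaus <- data.frame(start = starts - 1L, end = ends,
                         mean = means)
  structure(list(plateaus = plateaus,
                 rss = segmentation_rss(s1, s2, bounds, n),
                 n_steps = length(bounds),
                 quality = quality,
                 selected_steps = k_star),
            class = "step_fit")
}
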