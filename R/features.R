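#' Waveform features of one cardiac cycle
#'
#' Computes the eight waveform features used throughout the package from one
#' cardiac cycle of a uniformly sampled signal: maximum, minimum, mean
#' (trapezoidal integral over the cycle divided by the period), amplitude
#' (max - min), min-to-max time (rising limb duration; if the sampled
#' cycle's maximum precedes its minimum the time is measured modulo the
#' period, preserving the rising-limb meaning), pulsatility index
#' PI = (max - min)/mean, resistive index RI = (max - min)/max, and
#' max-to-mean ratio MMR = max/mean.  The identity PI = RI * MMR holds by
#' construction.  Plateau ties resolve to the first sample attaining the
#' extremum.
#'
#' @param ts a [timeseries()].
#' @param t_start cycle start time, s.
#' @param T cycle length, s.
#' @return An object of class `cycle_features`: a named list with fields
#'   `maximum`, `minimum`, `mean`, `amplitude`, `min_to_max_time`, `PI`,
#'   `RI`, `MMR`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' ts <- timeseries(t, 10 + sin(2 * pi * t / 0.8), "Pa")
#' extract_cycle(ts, 0.8, 0.8)
extract_cycle <- function(ts, t_start, T) {
  stopifnot(inherits(ts, "icp_ts"), T > 0)
  dt <- ts$t[2] - ts$t[1]
  eps <- dt * 1e-6
  if (t_start < ts$t[1] - eps || t_start + T > ts$t[length(ts$t)] + eps) {
    stop("time series does not cover the requested cycle [",
         format(t_start), ", ", format(t_start + T), "]", call. = FALSE)
  }
  in_win <- ts$t >= t_start - eps & ts$t < t_start + T - eps
  t <- ts$t[in_win]; v <- ts$v[in_win]
  if (length(v) < 4L) stop("cycle window contains too few samples",
                           call. = FALSE)
  # trapezoidal mean over the closed cycle (endpoint included for integration)
  i_end <- which(in_win)[length(t)] + 1L
  t_int <- c(t, ts$t[i_end]); v_int <- c(v, ts$v[i_end])
  mean_v <- sum(diff(t_int) * (v_int[-1] + v_int[-length(v_int)]) / 2) /
    (t_int[length(t_int)] - t_int[1])

  i_max <- which.max(v); i_min <- which.min(v)
  maximum <- v[i_max]; minimum <- v[i_min]
  amplitude <- maximum - minimum
  mmt <- if (amplitude == 0) 0 else {
    d <- t[i_max] - t[i_min]
    if (d < 0) d + T else d
  }
  pi_ <- ri <- NA_real_; mmr <- NA_real_
  if (amplitude == 0) {
    pi_ <- 0; ri <- 0; mmr <- 1
  } else {
    if (mean_v <= 0) {
      stop("cycle mean is non-positive; PI and MMR are undefined",
           call. = FALSE)
    }
    pi_ <- amplitude / mean_v
    ri <- amplitude / maximum
    mmr <- maximum / mean_v
  }
  structure(list(maximum = maximum, minimum = minimum, mean = mean_v,
                 amplitude = amplitude, min_to_max_time = mmt,
                 PI = pi_, RI = ri, MMR = mmr),
            class = "cycle_features")
}

#' @export
print.cycle_features <- function(x, digits = 4, ...) {
  cat("Cycle waveform features:\n")
  print(vapply(unclass(x), signif, 0, digits = digits))
  invisible(x)
}

#' @export
as.data.frame.cycle_features <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

feature_names <- function() {
  c("maximum", "minimum", "mean", "amplitude", "min_to_max_time",
    "PI", "RI", "MMR")
}

shape_feature_names <- function() c("min_to_max_time", "PI", "RI", "MMR")

#' Relative differences of features across conditions
#'
#' For features extracted at two or more intracranial-capacitance conditions
#' (fixed age and territory), computes the maximal relative difference
#' (max - min)/min of each feature across conditions, in percent.  This is
#' the statistic used to quantify the stability of the shape-relevant
#' features (min-to-max time, PI, RI, MMR) while ICP varies.
#'
#' @param features_by_condition a named list of `cycle_features` (one per
#'   condition).
#' @param features which features to tabulate; defaults to the four
#'   shape-relevant features.
#' @return A data frame with columns `feature` and `rel_diff_pct` (`NA` when
#'   a feature's minimum across conditions is not positive).
#' @export
relative_difference_table <- function(features_by_condition,
                                      features = shape_feature_names()) {
  stopifnot(length(features_by_condition) >= 2L)
  rows <- lapply(features, function(f) {
    v <- vapply(features_by_condition, function(cf) cf[[f]], 0)
    rd <- if (min(v) > 0) (max(v) - min(v)) / min(v) * 100 else NA_real_
    data.frame(feature = f, rel_diff_pct = rd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
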