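#' Simulate an acquisition campaign
#'
#' Emulates the recorded measurement sets: `n` noisy realizations of a
#' base sensor trace with additive white Gaussian noise at the detector
#' output (the default `n = 3000` mirrors the averaging used per
#' configuration in the experiments).
#'
#' @param base an [ia_trace()].
#' @param noise_sigma noise standard deviation in Pa (>= 0).
#' @param n number of acquisitions (>= 1).
#' @param seed integer seed (recorded in the result).
#' @return An object of class `ia_measurement_set`: `traces` is an
#'   `n x length(base)` matrix, plus `time`, `fs`, `noise_sigma`, `seed`.
#' @export
simulate_acquisitions <- function(base, noise_sigma, n = 3000, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  set.seed(seed)
  m <- length(base$pressure)
  noise <- if (noise_sigma > 0)
    matrix(stats::rnorm(n * m, 0, noise_sigma), n, m) else matrix(0, n, m)
  traces <- sweep(noise, 2, base$pressure, `+`)
  structure(list(traces = traces, time = base$time, fs = base$fs,
                 component = base$component, noise_sigma = noise_sigma,
                 n = n, seed = seed, base_meta = base$meta),
            class = "ia_measurement_set")
}

#' @export
print.ia_measurement_set <- function(x, ...) {
  cat(sprintf("<ia_measurement_set> %d acquisitions x %d samples, sigma=%g Pa, seed=%d\n",
              x$n, ncol(x$traces), x$noise_sigma, x$seed))
  invisible(x)
}

#' Grouped statistics with a 99% confidence interval
#'
#' Mirrors the measurement statistics: the acquisitions are subdivided
#' into `n_groups` groups of `group_size` (30 x 100 for the standard 3000
#' acquisitions), each group is averaged into one measurement trace, the
#' statistic is evaluated per group, and the mean with a Student-t
#' confidence half-width (99% by default, `n_groups - 1` degrees of
#' freedom) is returned.
#'
#' @param set an `ia_measurement_set`.
#' @param statistic function mapping an [ia_trace()] (a group-average) to
#'   a numeric scalar, e.g.
#'   `function(tr) amplitude_at_frequency(tr, f0 = 2.5e6)$amplitude`.
#' @param n_groups number of groups (default 30).
#' @param group_size acquisitions per group; default partitions all
#'   acquisitions evenly.
#' @param conf_level confidence level (default 0.99).
#' @return An object of class `ia_grouped_stats`: `values` (per group),
#'   `mean`, `ci_half_width`, `conf_level`, `n_groups`, `group_size`.
#' @export
grouped_stats <- function(set, statistic, n_groups = 30,
                          group_size = NULL, conf_level = 0.99) {
  if (is.null(group_size)) group_size <- floor(set$n / n_groups)
  if (n_groups * group_size > set$n)
    stop("insufficient acquisitions for the requested grouping")
  if (group_size < 1) stop("group_size must be >= 1")
  vals <- numeric(n_groups)
  for (g in seq_len(n_groups)) {
    rows <- ((g - 1) * group_size + 1):(g * group_size)
    avg <- colMeans(set$traces[rows, , drop = FALSE])
    tr <- ia_trace(set$time, avg, component = set$component)
    vals[g] <- statistic(tr)
  }
  m <- mean(vals)
  hw <- if (n_groups > 1) {
    stats::qt(1 - (1 - conf_level) / 2, n_groups - 1) *
      stats::sd(vals) / sqrt(n_groups)
  } else 0
  structure(list(values = vals, mean = m, ci_half_width = hw,
                 conf_level = conf_level, n_groups = n_groups,
                 group_size = group_size),
            class = "ia_grouped_stats")
}

#' @export
print.ia_grouped_stats <- function(x, ...) {
  cat(sprintf("<ia_grouped_stats> %d x %d: mean = %.6g +/- %.3g (%g%% CI)\n",
              x$n_groups, x$group_size, x$mean, x$ci_half_width,
              100 * x$conf_level))
  invisible(x)
}

#' Measurement-set CSV round trip
#'
#' Stores the acquisition block as one wide CSV (first column time, one
#' column per acquisition).
#'
#' @param set an `ia_measurement_set`.
#' @param path CSV file path.
#' @return the path (write) / the reconstructed set (read).
#' @export
measurement_set_write <- function(set, path) {
  d <- data.frame(time_s = set$time, t(set$traces))
  names(d) <- c("time_s", paste0("acq", seq_len(set$n)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname measurement_set_write
#' @export
measurement_set_read <- function(path) {
  d <- utils::read.csv(path)
  tr <- t(as.matrix(d[, -1, drop = FALSE]))
  structure(list(traces = tr, time = d[[1]],
                 fs = 1 / (d[[1]][2] - d[[1]][1]),
                 component = "imported", noise_sigma = NA_real_,
                 n = nrow(tr), seed = NA_integer_, base_meta = list()),
            class = "ia_measurement_set")
}
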