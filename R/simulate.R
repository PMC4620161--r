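#' AR(1) covariance matrix for the component estimates
#'
#' Entry (i, j) is sigma^2 * rho^|i - j|: neighboring components (adjacent
#' time points of the estimated HDR) are more correlated than distant ones,
#' a minimal structure that keeps the simulated curves smooth.
#'
#' @param m dimension (number of components).
#' @param sigma standard-deviation scale (> 0).
#' @param rho lag-1 correlation, |rho| < 1.
#' @return m x m symmetric positive-definite matrix.
#' @examples
#' ar1_covariance(7, sigma = 1, rho = 0.3)[1, 7]  # 0.3^6
#' @export
ar1_covariance <- function(m, sigma, rho) {
  stop_if_not_count(m, "m", min = 1L)
  if (!is_scalar_number(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is_scalar_number(rho) || abs(rho) >= 1) stop("rho must satisfy |rho| < 1", call. = FALSE)
  sigma^2 * rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

#' Parametric HDR shape
#'
#' Describes a smooth hemodynamic-response waveform as a difference of two
#' gamma-shaped bumps: a positive response peaking at `peak_time` and a
#' delayed, scaled undershoot. `undershoot_depth` is the depth of the dip
#' as a fraction of the peak; 0 gives a non-negative curve.
#'
#' @param peak_amplitude peak height (percent-signal-change units or
#'   arbitrary).
#' @param peak_time time to peak, seconds.
#' @param undershoot_depth undershoot depth as a fraction of peak, in
#'   [0, 1).
#' @param onset_delay delay before the response begins, seconds.
#' @param total_duration support of the waveform, seconds.
#' @param rise_width,undershoot_width gamma dispersion (seconds) of the
#'   response and undershoot bumps.
#' @param undershoot_delay seconds from peak to undershoot trough.
#' @return an `hdr_shape` object.
#' @export
hdr_shape <- function(peak_amplitude = 1, peak_time = 5, undershoot_depth = 0.1,
                      onset_delay = 0, total_duration = 16,
                      rise_width = 1.8, undershoot_width = 3.2,
                      undershoot_delay = 5) {
  if (!is_scalar_number(peak_time) || peak_time <= 0)
    stop("peak_time must be > 0", call. = FALSE)
  if (!is_scalar_number(undershoot_depth) || undershoot_depth < 0 || undershoot_depth >= 1)
    stop("undershoot_depth must be in [0, 1)", call. = FALSE)
  if (onset_delay < 0) stop("onset_delay must be >= 0", call. = FALSE)
  if (total_duration <= peak_time + onset_delay)
    stop("total_duration must exceed onset_delay + peak_time", call. = FALSE)
  structure(list(peak_amplitude = peak_amplitude, peak_time = peak_time,
                 undershoot_depth = undershoot_depth, onset_delay = onset_delay,
                 total_duration = total_duration, rise_width = rise_width,
                 undershoot_width = undershoot_width,
                 undershoot_delay = undershoot_delay),
            class = "hdr_shape")
}

# continuous difference-of-gammas waveform, normalized to peak_amplitude
hdr_waveform <- function(shape, t) {
  gamma_bump <- function(t, tp, width) {
    # unit-peak gamma-variate bump with mode at tp
    k <- tp / width
    out <- ifelse(t <= 0, 0, (t / tp)^k * exp((tp - t) / width))
    out[!is.finite(out)] <- 0
    out
  }
  ts <- t - shape$onset_delay
  h <- gamma_bump(ts, shape$peak_time, shape$rise_width) -
    shape$undershoot_depth *
      gamma_bump(ts, shape$peak_time + shape$undershoot_delay, shape$undershoot_width)
  h[t > shape$onset_delay + shape$total_duration] <- 0
  fine <- seq(0, shape$onset_delay + shape$total_duration, by = 0.01)
  hp <- gamma_bump(fine - shape$onset_delay, shape$peak_time, shape$rise_width) -
    shape$undershoot_depth *
      gamma_bump(fine - shape$onset_delay, shape$peak_time + shape$undershoot_delay,
                 shape$undershoot_width)
  shape$peak_amplitude * h / max(hp)
}

#' Sample an HDR shape at the TR grid
#'
#' Evaluates the waveform at times TR, 2*TR, ..., m*TR (the grid of an
#' estimated-shape fit whose basis functions start one TR after stimulus
#' onset, where a TENT estimate at onset itself is ~0).
#'
#' @param shape an [hdr_shape()].
#' @param tr sampling interval (scanner repetition time), seconds.
#' @param m number of samples (>= 2).
#' @param t0 time of the first sample; defaults to `tr`.
#' @return length-m numeric vector of curve samples.
#' @examples
#' hdr_curve(hdr_shape(peak_time = 5), tr = 2, m = 7)
#' @export
hdr_curve <- function(shape, tr = 2, m = 7, t0 = tr) {
  stopifnot(inherits(shape, "hdr_shape"))
  stop_if_not_count(m, "m", min = 2L)
  if (!is_scalar_number(tr) || tr <= 0) stop("tr must be > 0", call. = FALSE)
  t <- t0 + tr * (seq_len(m) - 1L)
  if (shape$onset_delay + shape$peak_time > max(t))
    stop("infeasible shape: peak_time falls beyond the sampled window", call. = FALSE)
  hdr_waveform(shape, t)
}

#' Simulation scenario for the group analysis study
#'
#' The six named scenarios mirror a standard Monte-Carlo design for
#' comparing group-level HDR tests, all with m = 7 components at TR = 2 s
#' and AR(1) correlation rho = 0.3:
#' \describe{
#'   \item{1a}{one group, small post-stimulus undershoot, sigma = 1.8}
#'   \item{1b}{one group, moderate undershoot, sigma = 1.8}
#'   \item{2a}{two homoscedastic groups, same shape, 2x amplitude
#'     difference, sigma = 0.5}
#'   \item{2b}{two homoscedastic groups, same peak amplitude, 2 s
#'     difference in peak location, sigma = 0.3}
#'   \item{3a}{as 2a but heteroscedastic (group-2 sigma scaled by
#'     `hetero_ratio`), group-1 sigma = 0.3}
#'   \item{3b}{as 2b but heteroscedastic, group-1 sigma = 0.3}
#' }
#' With `null_mode = TRUE` the tested effect is removed — a one-group mean
#' of zero, or two groups sharing the group-1 mean curve — while the
#' variance structure (including heteroscedasticity) is retained, for
#' false-positive-rate runs.
#'
#' @param name one of `"1a"`, `"1b"`, `"2a"`, `"2b"`, `"3a"`, `"3b"`, or
#'   `"custom"`.
#' @param null_mode remove the tested effect (see above).
#' @param hetero_ratio group-2 / group-1 sigma ratio for scenarios 3a/3b.
#' @param m,tr_seconds,rho grid and covariance parameters.
#' @param group_means,group_sigmas for `name = "custom"`: a list of one or
#'   two length-m mean vectors and the matching sigma values.
#' @return a `scenario` object with fields `name`, `group_means`,
#'   `group_sigmas`, `rho`, `m`, `tr_seconds`, `null_mode`.
#' @examples
#' sc <- make_scenario("2a")
#' sapply(sc$group_means, max)  # amplitudes 1 and 2
#' @export
make_scenario <- function(name = c("1a", "1b", "2a", "2b", "3a", "3b", "custom"),
                          null_mode = FALSE, hetero_ratio = 2,
                          m = 7, tr_seconds = 2, rho = 0.3,
                          group_means = NULL, group_sigmas = NULL) {
  name <- match.arg(name)
  base <- function(depth, delay = 0, amp = 1)
    hdr_curve(hdr_shape(peak_amplitude = amp, peak_time = 5,
                        undershoot_depth = depth, onset_delay = delay),
              tr = tr_seconds, m = m)
  if (name == "custom") {
    if (is.null(group_means) || is.null(group_sigmas))
      stop("custom scenario needs group_means and group_sigmas", call. = FALSE)
    means <- lapply(group_means, as.numeric)
    sigmas <- as.numeric(group_sigmas)
  } else {
    small <- 0.1; moderate <- 0.3
    spec <- switch(name,
      "1a" = list(means = list(base(small)), sigmas = 1.8),
      "1b" = list(means = list(base(moderate)), sigmas = 1.8),
      "2a" = list(means = list(base(small), 2 * base(small)), sigmas = c(0.5, 0.5)),
      "2b" = list(means = list(base(small), base(small, delay = tr_seconds)),
                  sigmas = c(0.3, 0.3)),
      "3a" = list(means = list(base(small), 2 * base(small)),
                  sigmas = c(0.3, 0.3 * hetero_ratio)),
      "3b" = list(means = list(base(small), base(small, delay = tr_seconds)),
                  sigmas = c(0.3, 0.3 * hetero_ratio)))
    means <- spec$means; sigmas <- spec$sigmas
  }
  if (length(means) != length(sigmas))
    stop("one sigma per group is required", call. = FALSE)
  if (null_mode)
    means <- if (length(means) == 1L) list(rep(0, length(means[[1]])))
             else rep(means[1], length(means))
  structure(list(name = name, group_means = means, group_sigmas = sigmas,
                 rho = rho, m = length(means[[1]]), tr_seconds = tr_seconds,
                 null_mode = null_mode),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario %s%s: %d group(s), m = %d, TR = %g s, rho = %g, sigma = %s\n",
              x$name, if (x$null_mode) " (null mode)" else "",
              length(x$group_means), x$m, x$tr_seconds, x$rho,
              paste(x$group_sigmas, collapse = "/")))
  invisible(x)
}

#' Draw per-subject component estimates for a scenario
#'
#' Each subject's length-m row is an independent draw from a multivariate
#' Gaussian with the group's mean curve and covariance
#' sigma_g^2 * rho^|i-j| (AR(1)). The draw is reproducible: the same seed
#' yields bit-identical output, and the caller's RNG state is untouched.
#'
#' @param sc a [make_scenario()] result.
#' @param n_per_group subjects per group (scalar, recycled across groups),
#'   >= 2.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a list with one [effect_matrix()] per group.
#' @export
simulate_betas <- function(sc, n_per_group, seed = NULL) {
  stopifnot(inherits(sc, "scenario"))
  n_per_group <- rep_len(n_per_group, length(sc$group_means))
  if (any(n_per_group < 2L)) stop("n_per_group must be >= 2", call. = FALSE)
  with_seed(seed, {
    lapply(seq_along(sc$group_means), function(g) {
      S <- ar1_covariance(sc$m, sc$group_sigmas[g], sc$rho)
      vals <- MASS::mvrnorm(n_per_group[g], mu = sc$group_means[[g]], Sigma = S)
      effect_matrix(vals,
                    subject_ids = sprintf("g%d_s%03d", g, seq_len(n_per_group[g])),
                    component_labels = paste0("t", seq_len(sc$m)))
    })
  })
}
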