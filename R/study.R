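#' Configure a false-positive-rate / power study
#'
#' @param scenarios character vector of scenario names (see
#'   [make_scenario()]).
#' @param methods subset of `c("MVT", "XUV", "XMV", "AUC", "L2D", "LME")`;
#'   LME is only valid for one-group scenarios.
#' @param n_grid per-group sample sizes to sweep.
#' @param reps Monte-Carlo replicates per cell (>= 100).
#' @param alpha nominal significance level.
#' @param seed master seed; per-replicate seeds are derived from it by a
#'   counter, so results are reproducible and cells are independent.
#' @param regimes which regimes to run: `"FPR"` (null-mode data),
#'   `"power"` (scenario means), or both.
#' @param correction sphericity correction used for XUV.
#' @param lme_ddf denominator-DF method for the LME omnibus test.
#' @param hetero_ratio group-2/group-1 sigma ratio for scenarios 3a/3b.
#' @return a `study_config` object.
#' @export
study_config <- function(scenarios, methods, n_grid, reps = 1000, alpha = 0.05,
                         seed = 1L, regimes = c("FPR", "power"),
                         correction = "GG",
                         lme_ddf = c("satterthwaite", "residual"),
                         hetero_ratio = 2) {
  methods <- match.arg(methods, c("MVT", "XUV", "XMV", "AUC", "L2D", "LME"),
                       several.ok = TRUE)
  regimes <- match.arg(regimes, c("FPR", "power"), several.ok = TRUE)
  lme_ddf <- match.arg(lme_ddf)
  stop_if_not_count(reps, "reps", min = 100L)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]", call. = FALSE)
  if ("LME" %in% methods) {
    two_group <- vapply(scenarios,
                        function(s) length(make_scenario(s)$group_means) > 1L, TRUE)
    if (any(two_group))
      stop("LME is only valid for one-group scenarios; offending: ",
           paste(scenarios[two_group], collapse = ", "), call. = FALSE)
  }
  structure(list(scenarios = scenarios, methods = methods,
                 n_grid = as.integer(n_grid), reps = as.integer(reps),
                 alpha = alpha, seed = as.integer(seed), regimes = regimes,
                 correction = correction, lme_ddf = lme_ddf,
                 hetero_ratio = hetero_ratio),
            class = "study_config")
}

# p-values of all requested methods on one simulated dataset (list of
# per-group effect matrices); returns a named numeric vector
analyze_dataset <- function(groups, methods, correction, lme_ddf) {
  if (length(groups) == 1L) {
    res <- run_shape_tests(groups[[1]], methods = methods,
                           correction = correction, lme_ddf = lme_ddf)
  } else {
    B <- effect_matrix(do.call(rbind, lapply(groups, unclass)))
    st <- data.frame(Subj = rownames(B),
                     Group = rep(paste0("g", seq_along(groups)),
                                 vapply(groups, nrow, 0L)))
    sp <- design_spec(between_factors = list(Group = unique(st$Group)))
    X <- encode_between_design(sp, st)
    res <- run_shape_tests(B, X, effect = "Group", methods = methods,
                           correction = correction, lme_ddf = lme_ddf)
  }
  stats::setNames(res$p, res$method)
}

#' Run the Monte-Carlo study
#'
#' For every (scenario, regime, n) cell, generates `reps` datasets
#' (null-mode for the FPR regime, the scenario's mean curves for power),
#' analyzes each with every requested method, and counts rejections at the
#' nominal level. Replicates that fail to fit (e.g., a singular matrix at a
#' tiny sample size) are counted as non-rejections and tallied in the
#' `failures` column rather than dropped.
#'
#' @param cfg a [study_config()].
#' @param verbose print progress per cell.
#' @return a `simulation_summary` data frame with columns scenario, method,
#'   n, regime, rejections, reps, failures, proportion, and the binomial
#'   standard error `se = sqrt(p(1-p)/reps)`.
#' @export
run_study <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  out <- list(); counter <- 0L
  for (sc_name in cfg$scenarios) {
    for (regime in cfg$regimes) {
      sc <- make_scenario(sc_name, null_mode = (regime == "FPR"),
                          hetero_ratio = cfg$hetero_ratio)
      for (n in cfg$n_grid) {
        rej <- stats::setNames(numeric(length(cfg$methods)), cfg$methods)
        fail <- stats::setNames(numeric(length(cfg$methods)), cfg$methods)
        for (r in seq_len(cfg$reps)) {
          counter <- counter + 1L
          groups <- simulate_betas(sc, n, seed = derive_seed(cfg$seed, counter))
          p <- tryCatch(
            suppressWarnings(suppressMessages(
              analyze_dataset(groups, cfg$methods, cfg$correction, cfg$lme_ddf))),
            error = function(e) NULL)
          if (is.null(p)) {
            fail <- fail + 1
          } else {
            ok <- !is.na(p)
            rej[names(p)[ok]] <- rej[names(p)[ok]] + (p[ok] < cfg$alpha)
            fail[names(p)[!ok]] <- fail[names(p)[!ok]] + 1
          }
        }
        cell <- data.frame(scenario = sc_name, method = cfg$methods, n = n,
                           regime = regime, rejections = as.integer(rej),
                           reps = cfg$reps, failures = as.integer(fail),
                           stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- cell
        if (verbose)
          message(sprintf("scenario %s, %s, n = %d done", sc_name, regime, n))
      }
    }
  }
  summary <- do.call(rbind, out)
  summary$proportion <- summary$rejections / summary$reps
  summary$se <- sqrt(summary$proportion * (1 - summary$proportion) / summary$reps)
  class(summary) <- c("simulation_summary", class(summary))
  summary
}

#' Rejection-rate curves over the sample-size grid
#'
#' Returns a plot-ready table of rejection proportions against n per
#' (scenario, method, regime), optionally smoothed with LOESS (second-order
#' local polynomials, as commonly used to display simulation curves);
#' smoothed values are clipped to [0, 1] and flagged in the `smoothed`
#' column.
#'
#' @param summary a [run_study()] result.
#' @param smoothing `"none"` or `"loess"` (requires >= 3 distinct n).
#' @param span LOESS span.
#' @return data frame with columns scenario, method, regime, n, proportion,
#'   smoothed.
#' @export
summarize_curves <- function(summary, smoothing = c("none", "loess"),
                             span = 1) {
  smoothing <- match.arg(smoothing)
  keys <- interaction(summary$scenario, summary$method, summary$regime, drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(summary)), keys), function(idx) {
    d <- summary[idx, , drop = FALSE]
    d <- d[order(d$n), ]
    prop <- d$proportion
    if (smoothing == "loess") {
      if (length(unique(d$n)) < 3L)
        stop("loess smoothing needs at least 3 sample sizes", call. = FALSE)
      fit <- stats::loess(proportion ~ n, data = d, span = span, degree = 2)
      prop <- pmin(1, pmax(0, stats::predict(fit)))
    }
    data.frame(scenario = d$scenario, method = d$method, regime = d$regime,
               n = d$n, proportion = prop, smoothed = smoothing == "loess",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Plot rejection-rate curves (FPR and power panels per scenario)
#'
#' @param summary a [run_study()] result.
#' @param smoothing passed to [summarize_curves()].
#' @return a ggplot object.
#' @export
plot_study <- function(summary, smoothing = "none") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_study requires ggplot2", call. = FALSE)
  curves <- summarize_curves(summary, smoothing)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$n, y = .data$proportion,
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(data = summarize_curves(summary)) +
    ggplot2::facet_grid(scenario ~ regime,
                        scales = "free_y") +
    ggplot2::labs(x = "subjects per group", y = "rejection proportion") +
    ggplot2::theme_minimal()
}

#' Write a simulation summary as delimited text
#' @param summary a [run_study()] result.
#' @param path output file; tab-separated.
#' @return the path, invisibly.
#' @export
write_study_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
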