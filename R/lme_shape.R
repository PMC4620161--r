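#' Linear mixed-effects model for one group of HDR profiles
#'
#' Fits the one-group mixed model beta_ij = alpha_j + delta_i + eps_ij in
#' which the m component effects are cell-mean coded (one fixed effect per
#' component, no intercept), delta_i is a random per-subject shift of the
#' whole profile, and eps_ij is residual noise. The implied marginal
#' covariance across a subject's components is compound symmetric. This
#' parameterization only exists for a single group with no other
#' explanatory variables: adding a grouping factor or covariate alongside
#' the m indicator variables would over-parameterize the model, so such
#' input is refused.
#'
#' Estimation is by REML (default) or ML through [lme4::lmer()]; in this
#' balanced design the fixed-effect estimates equal the column means of B.
#'
#' @param B an [effect_matrix()] (or matrix), n subjects x m components,
#'   n >= 3 and m >= 2.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param subject_table optional per-subject table; any non-constant column
#'   triggers the refusal above.
#' @return an `lme_fit` with elements `alpha` (fixed effects), `tau2`
#'   (random-shift variance, floored at 0), `sigma2` (residual variance),
#'   `vcov_alpha`, `dims`, `estimation`, and the underlying `model`.
#' @export
fit_lme_shape <- function(B, estimation = c("REML", "ML"), subject_table = NULL) {
  estimation <- match.arg(estimation)
  B <- as_effect_matrix(B)
  n <- nrow(B); m <- ncol(B)
  if (n < 3L) stop("at least 3 subjects are required for the LME fit", call. = FALSE)
  if (m < 2L) stop("at least 2 components are required for the LME fit", call. = FALSE)
  if (!is.null(subject_table)) {
    varying <- vapply(subject_table, function(v) length(unique(v)) > 1L, TRUE)
    varying["Subj"] <- FALSE
    if (any(varying))
      stop("the LME omnibus parameterization requires one group with no other ",
           "explanatory variables; remove: ",
           paste(names(subject_table)[varying], collapse = ", "), call. = FALSE)
  }
  long <- data.frame(
    value = as.vector(t(unclass(B))),
    subject = factor(rep(rownames(B), each = m), levels = rownames(B)),
    component = factor(rep(colnames(B), times = n), levels = colnames(B)))
  # a boundary fit (tau2 = 0) is a legitimate estimate here, not a failure
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  model <- lmerTest::lmer(value ~ 0 + component + (1 | subject), data = long,
                          REML = (estimation == "REML"), control = ctrl)
  vc <- lme4::VarCorr(model)
  alpha <- lme4::fixef(model)
  names(alpha) <- colnames(B)
  structure(list(alpha = alpha,
                 tau2 = as.numeric(vc$subject[1, 1]),
                 sigma2 = attr(vc, "sc")^2,
                 vcov_alpha = as.matrix(stats::vcov(model)),
                 dims = c(n = n, m = m),
                 estimation = estimation,
                 model = model),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("One-group LME fit (%s): n = %d subjects, m = %d components\n",
              x$estimation, x$dims["n"], x$dims["m"]))
  cat(sprintf("  subject-shift variance tau^2 = %.4g, residual sigma^2 = %.4g\n",
              x$tau2, x$sigma2))
  cat("  component effects alpha:\n")
  print(round(x$alpha, 4))
  invisible(x)
}

#' LME omnibus test of the whole HDR profile
#'
#' Tests H0: alpha_1 = ... = alpha_m = 0, i.e., no group-average response at
#' any component, with the Wald-type statistic
#' F = alpha' V^-1 alpha / m where V is the covariance of the fixed-effect
#' estimates. The denominator degrees of freedom use the Satterthwaite
#' approximation (default) or the residual DF of the balanced model,
#' n*m - m - 1; in this balanced one-group design the two nearly coincide
#' at typical sample sizes.
#'
#' @param fit an [fit_lme_shape()] result.
#' @param ddf `"satterthwaite"` or `"residual"`.
#' @return a [test_result()] with method `"LME"`.
#' @export
lme_omnibus <- function(fit, ddf = c("satterthwaite", "residual")) {
  stopifnot(inherits(fit, "lme_fit"))
  ddf <- match.arg(ddf)
  m <- fit$dims[["m"]]; n <- fit$dims[["n"]]
  V <- fit$vcov_alpha
  f <- tryCatch(drop(crossprod(fit$alpha, solve(V, fit$alpha))) / m,
                error = function(e) stop("singular fixed-effect covariance", call. = FALSE))
  df2 <- if (ddf == "satterthwaite") {
    ct <- lmerTest::contest(fit$model, diag(m), joint = TRUE)
    ct$DenDF
  } else n * m - m - 1
  test_result("LME", f, m, df2, label = "omnibus")
}
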