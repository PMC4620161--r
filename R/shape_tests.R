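#' Result of a group-level HDR shape test
#'
#' Bundles an F statistic with its (possibly non-integer) degrees of
#' freedom, the upper-tail p-value, and the standard-normal equivalent Z
#' used to compare tests with different degrees of freedom on a common
#' scale. Constructed internally by the test functions.
#'
#' @param method test family label.
#' @param statistic F value (>= 0).
#' @param df1,df2 numerator/denominator degrees of freedom (> 0); real
#'   valued so that sphericity-scaled DFs can be carried.
#' @param epsilon sphericity factor, or `NA` when not applicable.
#' @param label hypothesis label.
#' @return a `test_result` object; also a one-row data frame via
#'   [as.data.frame.test_result()].
#' @export
test_result <- function(method, statistic, df1, df2, epsilon = NA_real_,
                        label = "") {
  if (!is_scalar_number(df1) || !is_scalar_number(df2) || df1 <= 0 || df2 <= 0)
    stop("degrees of freedom must be positive", call. = FALSE)
  if (!is_scalar_number(statistic) || statistic < 0)
    stop("F statistic must be a non-negative number", call. = FALSE)
  log_p <- stats::pf(statistic, df1, df2, lower.tail = FALSE, log.p = TRUE)
  structure(list(method = method, statistic = statistic,
                 df1 = df1, df2 = df2, epsilon = epsilon,
                 p = exp(log_p),
                 z = stats::qnorm(log_p, lower.tail = FALSE, log.p = TRUE),
                 label = label),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s%s: F(%.4g, %.4g) = %.4g, p = %.4g, Z = %.3f%s\n",
              x$method, if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$df1, x$df2, x$statistic, x$p, x$z,
              if (is.finite(x$epsilon)) sprintf(", epsilon = %.3f", x$epsilon) else ""))
  invisible(x)
}

#' @rdname test_result
#' @param x a `test_result`
#' @param ... unused
#' @export
as.data.frame.test_result <- function(x, ...) {
  data.frame(method = x$method, label = x$label, statistic = x$statistic,
             df1 = x$df1, df2 = x$df2, epsilon = x$epsilon, p = x$p, z = x$z,
             stringsAsFactors = FALSE)
}

#' Convert an F statistic to its standard-normal equivalent
#'
#' Maps the upper-tail F probability through the standard-normal quantile,
#' `z = qnorm(1 - p)`, computed on the log scale so that very small
#' p-values remain finite down to double-precision underflow. The Z value
#' depends on the F statistic only through its p-value, making tests with
#' different degrees of freedom directly comparable.
#'
#' @param statistic F value (>= 0), vectorized.
#' @param df1,df2 positive degrees of freedom.
#' @return numeric vector of Z equivalents.
#' @examples
#' f_to_z(qf(0.95, 3, 20), 3, 20)  # ~ qnorm(0.95)
#' @export
f_to_z <- function(statistic, df1, df2) {
  if (any(!is.finite(df1)) || any(!is.finite(df2)) || any(df1 <= 0) || any(df2 <= 0))
    stop("degrees of freedom must be positive", call. = FALSE)
  if (any(statistic < 0)) stop("F statistic must be non-negative", call. = FALSE)
  log_p <- stats::pf(statistic, df1, df2, lower.tail = FALSE, log.p = TRUE)
  stats::qnorm(log_p, lower.tail = FALSE, log.p = TRUE)
}

# hypothesis and error SSP matrices for the general linear hypothesis
# L A M = 0 under an mvm_fit
mlh_ssp <- function(fit, L, M) {
  q <- fit$dims[["q"]]; m <- fit$dims[["m"]]; n <- fit$dims[["n"]]
  if (ncol(L) != q) stop("L must have q = ", q, " columns", call. = FALSE)
  if (nrow(M) != m) stop("M must have m = ", m, " rows", call. = FALSE)
  LAM <- L %*% fit$coef %*% M
  W <- L %*% fit$xtx_inverse %*% t(L)
  H <- crossprod(LAM, solve(W, LAM))
  E <- crossprod(M, fit$residual_ssp %*% M)
  # magnitude of the untransformed problem, used to recognize an exactly
  # (up to roundoff) null tested effect without inverting a degenerate E
  scale <- sum(diag(fit$residual_ssp)) + sum(fit$coef^2)
  list(H = H, E = E, g = nrow(L), c = ncol(M), nu = n - q,
       zero_effect = sum(diag(H)) <= 1e-14 * scale)
}

# F approximation for a multivariate statistic; exact Hotelling T2 when the
# hypothesis has a single between-subject contrast row (g = 1)
multivariate_f <- function(ssp, statistic = c("pillai", "wilks")) {
  statistic <- match.arg(statistic)
  g <- ssp$g; cc <- ssp$c; nu <- ssp$nu
  if (nu < cc)
    stop("multivariate test infeasible: more components than error DF ",
         sprintf("(c = %d, error DF = %d); reduce M or add subjects", cc, nu),
         call. = FALSE)
  zero_effect <- ssp$zero_effect
  Einv_H <- if (zero_effect) matrix(0, cc, cc) else
    tryCatch(solve(ssp$E, ssp$H),
             error = function(e) stop("singular error SSP matrix", call. = FALSE))
  if (g == 1L) {
    T2 <- max(0, nu * sum(diag(Einv_H)))
    df1 <- cc; df2 <- nu - cc + 1
    return(list(f = T2 * df2 / (nu * cc), df1 = df1, df2 = df2))
  }
  s <- min(g, cc)
  if (statistic == "pillai") {
    V <- if (zero_effect) 0 else sum(diag(solve(ssp$H + ssp$E, ssp$H)))
    mm <- (abs(g - cc) - 1) / 2
    nn <- (nu - cc - 1) / 2
    df1 <- s * (2 * mm + s + 1)
    df2 <- s * (2 * nn + s + 1)
    f <- (df2 / df1) * V / (s - V)
  } else {
    lambda <- if (zero_effect) 1 else det(ssp$E) / det(ssp$E + ssp$H)
    r <- nu - (cc - g + 1) / 2
    t <- if (cc^2 + g^2 - 5 > 0) sqrt((cc^2 * g^2 - 4) / (cc^2 + g^2 - 5)) else 1
    df1 <- cc * g
    df2 <- r * t - (cc * g - 2) / 2
    f <- (df2 / df1) * (1 - lambda^(1 / t)) / lambda^(1 / t)
  }
  list(f = f, df1 = df1, df2 = df2)
}

#' Whole-profile multivariate test (MVT)
#'
#' Tests the m component estimates jointly, treating them as simultaneous
#' response variables: the one-sample prototype H0: alpha_1 = ... =
#' alpha_m = 0 and the two-sample prototype of equal group centroids are
#' Hotelling T-squared tests, computed exactly and reported as F with
#' degrees of freedom (c, n - c - q + 1) where c = rank(M) (c = m for the
#' full profile). Hypotheses with several between-subject contrast rows use
#' Pillai's trace (default) or Wilks' lambda with the standard F
#' approximation.
#'
#' @param fit an [fit_mvm()] result.
#' @param hyp a [hypothesis_spec()]; M defaults to the identity (whole
#'   profile).
#' @param statistic multivariate statistic for multi-row L.
#' @return a [test_result()].
#' @export
mvt_general <- function(fit, hyp, statistic = c("pillai", "wilks")) {
  stopifnot(inherits(fit, "mvm_fit"), inherits(hyp, "hypothesis_spec"))
  ssp <- mlh_ssp(fit, hyp$L, hyp$M)
  res <- multivariate_f(ssp, statistic)
  test_result("MVT", res$f, res$df1, res$df2, label = hyp$label)
}

#' Effect-by-component interaction test, univariate form (XUV)
#'
#' Tests whether the HDR profiles are parallel (equivalently, whether the
#' tested effect is constant across components) with the classical
#' repeated-measures F: the data are transformed by an orthonormal basis of
#' zero-sum component contrasts and the univariate F pools the transformed
#' variables, with nominal degrees of freedom (g*c, c*(n - q)), c = m - 1
#' for the full interaction. Because pooling assumes sphericity of the
#' contrast covariance, the Greenhouse-Geisser (default) or Huynh-Feldt
#' estimate of the sphericity factor epsilon multiplies both degrees of
#' freedom; the estimate is recorded in the result.
#'
#' @inheritParams mvt_general
#' @param hyp a [hypothesis_spec()] whose M columns are zero-sum contrasts
#'   among the components (any basis of the same span gives identical
#'   results; see [component_contrasts()]).
#' @param correction sphericity correction: `"GG"` (default), `"HF"`, or
#'   `"none"`.
#' @return a [test_result()] with the `epsilon` field set (1 when
#'   `correction = "none"`).
#' @export
xuv_interaction <- function(fit, hyp, correction = c("GG", "HF", "none")) {
  stopifnot(inherits(fit, "mvm_fit"), inherits(hyp, "hypothesis_spec"))
  correction <- match.arg(correction)
  M <- hyp$M
  if (ncol(M) == 0L) stop("M has no contrast columns", call. = FALSE)
  if (!is_zero_sum(M))
    stop("XUV requires zero-sum component contrasts in M", call. = FALSE)
  M <- orthonormalize(M)
  ssp <- mlh_ssp(fit, hyp$L, M)
  g <- ssp$g; cc <- ssp$c; nu <- ssp$nu
  df1 <- g * cc
  df2 <- cc * nu
  trH <- sum(diag(ssp$H)); trE <- sum(diag(ssp$E))
  f <- if (ssp$zero_effect) 0 else (trH / df1) / (trE / df2)
  eps <- 1
  if (correction != "none" && trE > 0) {
    S <- ssp$E / nu
    eps <- sum(diag(S))^2 / (cc * sum(S * S))        # Greenhouse-Geisser (Box)
    if (correction == "HF")
      eps <- min(1, ((nu + 1) * cc * eps - 2) / (cc * (nu - cc * eps)))
    eps <- min(1, max(eps, 1 / cc))
  }
  test_result("XUV", f, eps * df1, eps * df2, epsilon = eps, label = hyp$label)
}

#' Effect-by-component interaction test, multivariate form (XMV)
#'
#' The same parallelism hypothesis as [xuv_interaction()], tested instead by
#' treating the c = m - 1 contrast-transformed variables as simultaneous
#' responses in a MAN(C)OVA: exact Hotelling T-squared for a single contrast
#' row (F with df (c, n - c - q + 1)), Pillai/Wilks otherwise. Requires
#' n - q >= c, which fails for rank-deficient reconstructed estimates or
#' very small samples.
#'
#' @inheritParams xuv_interaction
#' @param statistic multivariate statistic for multi-row L.
#' @return a [test_result()].
#' @export
xmv_interaction <- function(fit, hyp, statistic = c("pillai", "wilks")) {
  stopifnot(inherits(fit, "mvm_fit"), inherits(hyp, "hypothesis_spec"))
  M <- hyp$M
  if (!is_zero_sum(M))
    stop("XMV requires zero-sum component contrasts in M", call. = FALSE)
  ssp <- mlh_ssp(fit, hyp$L, orthonormalize(M))
  res <- multivariate_f(ssp, statistic)
  test_result("XMV", res$f, res$df1, res$df2, label = hyp$label)
}

#' Dimension reductions of the component estimates
#'
#' Collapses each subject's m component estimates to a single value:
#' a weighted sum (`method = "linear"`; the default unit weights give the
#' area under the estimated HDR curve, AUC), or the Euclidean norm of the
#' row (`method = "l2d"`), optionally signed by the sign of a designated
#' component (the canonical-basis coefficient for adjusted-shape
#' estimates).
#'
#' @param B an [effect_matrix()] or numeric matrix.
#' @param method `"linear"` or `"l2d"`.
#' @param weights length-m weight vector for linear reduction (default all
#'   ones, i.e., AUC).
#' @param signed attach the sign of `sign_component` to the norm (L2D for
#'   adjusted-shape estimates); unsigned norms are always >= 0.
#' @param sign_component index of the component whose sign is attached.
#' @return numeric vector with one value per subject.
#' @examples
#' B <- rbind(c(1, 2, -1), c(-3, 4, 0))
#' reduce_components(B)                       # AUC: 2, 1
#' reduce_components(B, method = "l2d")       # norms
#' @export
reduce_components <- function(B, method = c("linear", "l2d"), weights = NULL,
                              signed = FALSE, sign_component = 1L) {
  method <- match.arg(method)
  B <- as.matrix(B)
  m <- ncol(B)
  if (method == "linear") {
    weights <- weights %||% rep(1, m)
    if (length(weights) != m)
      stop("weights must have one entry per component", call. = FALSE)
    if (all(weights == 0)) stop("weights must not all be zero", call. = FALSE)
    return(drop(B %*% weights))
  }
  v <- sqrt(rowSums(B^2))
  if (signed) {
    if (sign_component < 1L || sign_component > m)
      stop("sign_component out of range", call. = FALSE)
    v <- sign(B[, sign_component]) * v
  }
  unname(v)
}

#' Univariate test on reduced per-subject values
#'
#' Runs the univariate general linear test of the contrast L on a length-n
#' vector of reduced values (AUC sums, L2D norms, or any other per-subject
#' summary) under the same between-subject design X, yielding F with
#' degrees of freedom (g, n - q); for a single contrast this is the square
#' of the corresponding one-/two-sample or covariate-adjusted t test.
#'
#' @param values numeric length-n vector.
#' @param X n x q design matrix.
#' @param L contrast row(s) over the design columns (default: intercept).
#' @param method label recorded in the result (e.g., `"AUC"`, `"L2D"`).
#' @param label hypothesis label.
#' @return a [test_result()].
#' @export
reduced_test <- function(values, X, L = NULL, method = "AUC", label = "") {
  values <- as.numeric(values)
  X <- as.matrix(X)
  n <- length(values); q <- ncol(X)
  if (nrow(X) != n) stop("values and design matrix disagree on n", call. = FALSE)
  if (n <= q) stop("insufficient subjects for design (need n > q)", call. = FALSE)
  if (is.null(L)) L <- matrix(c(1, rep(0, q - 1)), 1)
  if (is.vector(L)) L <- matrix(L, nrow = 1L)
  qrX <- qr(X)
  if (qrX$rank < q) stop("singular design: X is rank deficient", call. = FALSE)
  b <- qr.coef(qrX, values)
  rss <- sum(qr.resid(qrX, values)^2)
  s2 <- rss / (n - q)
  Lb <- L %*% b
  W <- L %*% chol2inv(qr.R(qrX)) %*% t(L)
  f <- drop(crossprod(Lb, solve(W, Lb))) / (nrow(L) * s2)
  test_result(method, f, nrow(L), n - q, label = label)
}

#' Run a battery of shape tests on one dataset
#'
#' Convenience driver used by the simulation study and the voxelwise mode:
#' given an effect matrix, a between-subject design, and the name of the
#' tested effect, runs any subset of the test families and returns one row
#' per test.
#'
#' For the tested effect, MVT uses the whole profile (M = identity),
#' XUV/XMV use the orthonormal component contrasts, AUC the unit-weight
#' reduction, L2D the (unsigned by default) norm reduction, and LME the
#' mixed-effects omnibus test (one intercept-only group required).
#'
#' @param B an [effect_matrix()] or matrix.
#' @param X design matrix (default: intercept only); see
#'   [encode_between_design()].
#' @param effect tested between-subject effect: name of a term recorded in
#'   `attr(X, "term_cols")`, or integer design-column indices. Default: the
#'   intercept.
#' @param methods subset of `c("MVT", "XUV", "XMV", "AUC", "L2D", "LME")`.
#' @param correction sphericity correction for XUV.
#' @param statistic multivariate statistic for multi-row contrasts.
#' @param l2d_signed,l2d_sign_component signed-norm options for L2D.
#' @param lme_ddf denominator-DF method for the LME omnibus test.
#' @return data frame with columns method, label, statistic, df1, df2,
#'   epsilon, p, z.
#' @examples
#' B <- simulate_betas(make_scenario("1a"), n_per_group = 12, seed = 1)[[1]]
#' run_shape_tests(B, methods = c("MVT", "XUV", "AUC"))
#' @export
run_shape_tests <- function(B, X = NULL, effect = NULL,
                            methods = c("MVT", "XUV", "XMV", "AUC", "L2D"),
                            correction = c("GG", "HF", "none"),
                            statistic = c("pillai", "wilks"),
                            l2d_signed = FALSE, l2d_sign_component = 1L,
                            lme_ddf = c("satterthwaite", "residual")) {
  B <- as_effect_matrix(B)
  methods <- match.arg(methods, c("MVT", "XUV", "XMV", "AUC", "L2D", "LME"),
                       several.ok = TRUE)
  correction <- match.arg(correction)
  statistic <- match.arg(statistic)
  lme_ddf <- match.arg(lme_ddf)
  n <- nrow(B); m <- ncol(B)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  q <- ncol(X)
  term_cols <- attr(X, "term_cols")
  cols <- if (is.null(effect)) 1L
          else if (is.numeric(effect)) as.integer(effect)
          else {
            if (is.null(term_cols) || is.null(term_cols[[effect]]))
              stop("effect '", effect, "' not found in the design terms", call. = FALSE)
            term_cols[[effect]]
          }
  L <- diag(q)[cols, , drop = FALSE]
  label <- if (is.character(effect)) effect else colnames(X)[cols[1]] %||% ""

  fit <- NULL
  need_fit <- any(c("MVT", "XUV", "XMV") %in% methods)
  if (need_fit) fit <- fit_mvm(B, X)
  out <- list()
  for (meth in methods) {
    res <- switch(meth,
      MVT = mvt_general(fit, hypothesis_spec(L, m = m, label = label),
                        statistic = statistic),
      XUV = xuv_interaction(fit, hypothesis_spec(L, component_contrasts(m),
                                                 label = label),
                            correction = correction),
      XMV = xmv_interaction(fit, hypothesis_spec(L, component_contrasts(m),
                                                 label = label),
                            statistic = statistic),
      AUC = reduced_test(reduce_components(B, "linear"), X, L,
                         method = "AUC", label = label),
      L2D = reduced_test(reduce_components(B, "l2d", signed = l2d_signed,
                                           sign_component = l2d_sign_component),
                         X, L, method = "L2D", label = label),
      LME = {
        if (q != 1L)
          stop("LME omnibus test requires a single group with no other explanatory variables",
               call. = FALSE)
        lme_omnibus(fit_lme_shape(B), ddf = lme_ddf)
      })
    out[[meth]] <- as.data.frame(res)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write shape-test results as delimited text
#'
#' @param results data frame from [run_shape_tests()].
#' @param path output file; tab-separated.
#' @return the path, invisibly.
#' @export
write_test_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
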