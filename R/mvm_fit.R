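#' Fit the multivariate linear model B = XA + D
#'
#' Jointly regresses the m component columns of the effect matrix on the
#' shared between-subject design matrix X by least squares, and accumulates
#' the sufficient statistics every shape test consumes: the q x m coefficient
#' matrix A-hat, the m x m residual sum-of-squares-and-products (SSP) matrix
#' E = (B - X A-hat)' (B - X A-hat) with n - q error degrees of freedom, and
#' (X'X)^-1.
#'
#' Fitting the columns jointly is identical to fitting each column separately
#' against X; the multivariate structure only enters through E.
#'
#' @param B an [effect_matrix()] (or numeric matrix), n x m.
#' @param X numeric design matrix, n x q, full column rank (see
#'   [encode_between_design()]); a plain column of ones for a one-group
#'   analysis.
#' @return an `mvm_fit` object with elements `coef`, `residual_ssp`,
#'   `design`, `xtx_inverse`, and `dims = c(n, m, q)`.
#' @examples
#' B <- effect_matrix(matrix(rnorm(30), 10, 3))
#' fit <- fit_mvm(B, matrix(1, 10, 1))
#' fit$coef  # column means
#' @export
fit_mvm <- function(B, X) {
  B <- as_effect_matrix(B)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(B); m <- ncol(B); q <- ncol(X)
  if (nrow(X) != n)
    stop("design matrix and effect matrix disagree on the number of subjects",
         call. = FALSE)
  if (n <= q)
    stop("insufficient subjects for design (need n > q)", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < q)
    stop("singular design: X is rank deficient", call. = FALSE)
  coef <- qr.coef(qrX, unclass(B))
  resid <- unclass(B) - X %*% coef
  E <- crossprod(resid)
  xtx_inv <- chol2inv(qr.R(qrX))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  rownames(coef) <- colnames(X)
  structure(list(coef = coef, residual_ssp = E, design = X,
                 xtx_inverse = xtx_inv,
                 dims = c(n = n, m = m, q = q),
                 term_cols = attr(X, "term_cols")),
            class = "mvm_fit")
}

#' @export
print.mvm_fit <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Multivariate linear model fit: n = %d subjects, m = %d components, q = %d design columns\n",
              d["n"], d["m"], d["q"]))
  cat("Coefficient matrix A-hat:\n")
  print(x$coef, digits = 4)
  invisible(x)
}
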