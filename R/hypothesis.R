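#' Specify a general linear hypothesis L A M = 0
#'
#' The between-subject contrast rows L (g x q) select which rows of the
#' coefficient matrix A are tested; the within-subject transform M (m x c)
#' selects which combination of components is tested. The whole-profile
#' multivariate test uses M = identity; the effect-by-component interaction
#' tests use a basis of zero-sum contrasts among the components (see
#' [component_contrasts()]).
#'
#' @param L numeric matrix (or vector, taken as one row), g x q, full row
#'   rank.
#' @param M numeric matrix (or vector, taken as one column), m x c, full
#'   column rank; defaults to the identity when `m` is supplied.
#' @param label short description carried into results.
#' @param m number of components, used only to build the default identity M.
#' @return a `hypothesis_spec` object.
#' @export
hypothesis_spec <- function(L, M = NULL, label = "", m = NULL) {
  if (is.vector(L)) L <- matrix(L, nrow = 1L)
  L <- as.matrix(L)
  if (is.null(M)) {
    if (is.null(m)) stop("supply M or the number of components m", call. = FALSE)
    M <- diag(m)
  }
  if (is.vector(M)) M <- matrix(M, ncol = 1L)
  M <- as.matrix(M)
  if (qr(L)$rank < nrow(L)) stop("contrast rows L are not linearly independent", call. = FALSE)
  if (qr(M)$rank < ncol(M)) stop("transform columns M are not linearly independent", call. = FALSE)
  structure(list(L = L, M = M, label = label), class = "hypothesis_spec")
}

#' Orthonormal zero-sum contrasts among m components
#'
#' Returns the m x (m-1) orthonormal polynomial contrast basis used by
#' default for the effect-by-component interaction tests. Any other zero-sum
#' contrast basis spanning the same space yields identical test results.
#'
#' @param m number of components (>= 2)
#' @return m x (m-1) matrix with orthonormal, zero-sum columns.
#' @export
component_contrasts <- function(m) {
  stop_if_not_count(m, "m", min = 2L)
  C <- stats::contr.poly(m)
  colnames(C) <- paste0("c", seq_len(m - 1L))
  C
}

# orthonormalize the columns of a contrast matrix, preserving its span
orthonormalize <- function(M) {
  qr.Q(qr(M))[, seq_len(qr(M)$rank), drop = FALSE]
}

is_zero_sum <- function(M, tol = 1e-8) {
  all(abs(colSums(M)) < tol * pmax(1, apply(abs(M), 2, max)))
}
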