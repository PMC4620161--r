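#' Describe the between-subject design
#'
#' A `design_spec` records the between-subject side of the multivariate model
#' B = XA + D: grouping factors, quantitative covariates with their centering
#' policy, and interactions. Within-subject factors (whose flattened level
#' combinations form the columns of B) are recorded for bookkeeping only;
#' they never enter the design matrix X.
#'
#' Factor coding defaults to effect (deviation) coding, which makes the
#' intercept the average effect across groups; treatment (dummy) coding is
#' available. Covariates can be centered globally, within the levels of a
#' grouping factor (so that a group effect is interpreted at each group's own
#' covariate mean), or not at all.
#'
#' @param between_factors named list; each element is the character vector of
#'   declared levels for that factor. May be empty.
#' @param covariates named list; each element is a centering policy, either a
#'   string (`"global"`, `"within"`, `"none"`) or a list
#'   `list(center = "within", by = "<factor>")`. `"within"` without `by`
#'   centers within the levels of the first declared factor.
#' @param interactions list of character vectors naming the interacting
#'   variables (factors and/or covariates).
#' @param within_factors named list of within-subject factors, each element
#'   the number of levels (or the character vector of level labels); the
#'   row-major flattening over the declared order defines the component
#'   labels of the effect matrix.
#' @param coding `"effect"` or `"treatment"` factor coding.
#' @return a `design_spec` object.
#' @seealso [encode_between_design()]
#' @export
design_spec <- function(between_factors = list(), covariates = list(),
                        interactions = list(),
                        within_factors = list(),
                        coding = c("effect", "treatment")) {
  coding <- match.arg(coding)
  if (length(between_factors) && is.null(names(between_factors)))
    stop("between_factors must be a named list", call. = FALSE)
  if (length(covariates) && is.null(names(covariates)))
    stop("covariates must be a named list", call. = FALSE)
  covariates <- lapply(covariates, function(p) {
    if (is.character(p)) p <- list(center = p)
    p$center <- match.arg(p$center, c("global", "within", "none"))
    p
  })
  structure(list(between_factors = between_factors, covariates = covariates,
                 interactions = interactions, within_factors = within_factors,
                 coding = coding),
            class = "design_spec")
}

#' Component labels implied by the declared within-subject factors
#' @param spec a [design_spec()]
#' @return character vector of flattened cell labels (row-major over the
#'   declared factor order), or `NULL` when no within-subject factors were
#'   declared.
#' @export
within_cell_labels <- function(spec) {
  wf <- spec$within_factors
  if (!length(wf)) return(NULL)
  levs <- lapply(names(wf), function(nm) {
    l <- wf[[nm]]
    if (is.numeric(l)) paste0(nm, seq_len(l)) else paste0(nm, ".", as.character(l))
  })
  # row-major over declared order: the first factor varies slowest
  grid <- expand.grid(rev(levs), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(levs)), drop = FALSE], 1L, paste, collapse = "_")
}

code_factor <- function(x, levels, name, coding) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad))
    stop(sprintf("unknown level(s) for factor '%s': %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  f <- factor(x, levels = levels)
  k <- length(levels)
  contr <- if (coding == "effect") stats::contr.sum(k) else stats::contr.treatment(k)
  cols <- contr[as.integer(f), , drop = FALSE]
  colnames(cols) <- if (coding == "effect")
    paste0(name, "_", levels[-k], "v", levels[k]) else paste0(name, "_", levels[-1])
  cols
}

#' Build the between-subject design matrix X
#'
#' Encodes a [design_spec()] against a per-subject table into the n x q
#' design matrix of the multivariate model, with columns ordered as
#' intercept, factor codings, centered covariates, then interactions.
#' Covariates under the within-group policy have exactly zero mean inside
#' each level of their grouping factor.
#'
#' @param spec a [design_spec()]
#' @param subject_table data frame with one row per subject containing every
#'   declared variable (a `Subj` column, if present, is used for row labels).
#' @return numeric matrix X with full column rank q; attribute `term_cols`
#'   maps each model term to its column indices (used to form between-subject
#'   contrast rows L for the tests).
#' @examples
#' st <- data.frame(Subj = paste0("s", 1:4), Group = c("a", "a", "b", "b"))
#' sp <- design_spec(between_factors = list(Group = c("a", "b")))
#' encode_between_design(sp, st)
#' @export
encode_between_design <- function(spec, subject_table) {
  stopifnot(inherits(spec, "design_spec"), is.data.frame(subject_table))
  n <- nrow(subject_table)
  need <- c(names(spec$between_factors), names(spec$covariates))
  miss <- setdiff(need, names(subject_table))
  if (length(miss))
    stop("subject table lacks declared variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(subject_table[need]))
    stop("missing values in between-subject variables", call. = FALSE)

  blocks <- list(`(Intercept)` = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  for (nm in names(spec$between_factors))
    blocks[[nm]] <- code_factor(subject_table[[nm]], spec$between_factors[[nm]],
                                nm, spec$coding)
  for (nm in names(spec$covariates)) {
    pol <- spec$covariates[[nm]]
    v <- subject_table[[nm]]
    if (!is.numeric(v)) stop(sprintf("covariate '%s' is not numeric", nm), call. = FALSE)
    v <- switch(pol$center,
      none = v,
      global = v - mean(v),
      within = {
        by <- pol$by %||% names(spec$between_factors)[1]
        if (is.null(by))
          stop(sprintf("within-group centering of '%s' needs a grouping factor", nm),
               call. = FALSE)
        stats::ave(v, subject_table[[by]], FUN = function(z) z - mean(z))
      })
    blocks[[nm]] <- matrix(v, n, 1, dimnames = list(NULL, nm))
  }
  for (ia in spec$interactions) {
    miss <- setdiff(ia, names(blocks))
    if (length(miss))
      stop("interaction references undeclared variable(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    cols <- blocks[[ia[1]]]
    for (v in ia[-1]) {
      right <- blocks[[v]]
      cols <- do.call(cbind, lapply(seq_len(ncol(cols)), function(i) {
        out <- cols[, i] * right
        colnames(out) <- paste(colnames(cols)[i], colnames(right), sep = ":")
        out
      }))
    }
    blocks[[paste(ia, collapse = ":")]] <- cols
  }

  X <- do.call(cbind, blocks)
  term_cols <- split(seq_len(ncol(X)),
                     rep(names(blocks), vapply(blocks, ncol, 0L)))[names(blocks)]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (ncol(X) >= n)
    stop("insufficient subjects for design (q >= n)", call. = FALSE)
  if ("Subj" %in% names(subject_table))
    rownames(X) <- as.character(subject_table$Subj)
  attr(X, "term_cols") <- term_cols
  X
}
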