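#' Per-subject effect estimates for the HDR components
#'
#' An `effect_matrix` holds the n x m matrix B of group-level input data:
#' one row per subject, one column per within-subject cell (typically the m
#' effect estimates associated with the m basis functions used to model the
#' hemodynamic response, or the flattened level combinations of several
#' within-subject factors).
#'
#' @param values numeric matrix (or coercible), n subjects by m components.
#'   No missing values are allowed; listwise deletion is the caller's
#'   responsibility (see [read_effect_table()]).
#' @param subject_ids optional length-n vector of unique subject labels;
#'   defaults to existing rownames or `S1..Sn`.
#' @param component_labels optional length-m vector of cell labels; defaults
#'   to existing colnames or `C1..Cm`. When several within-subject factors
#'   are flattened onto the columns, the labels should record the level
#'   combination (row-major over the declared factor order).
#' @return an `effect_matrix`: a numeric matrix with subject and component
#'   dimnames.
#' @examples
#' B <- effect_matrix(matrix(rnorm(12), 4, 3))
#' n_subjects(B); n_components(B)
#' @export
effect_matrix <- function(values, subject_ids = NULL, component_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("effect values must be numeric", call. = FALSE)
  if (anyNA(values))
    stop("effect matrix must not contain missing values", call. = FALSE)
  n <- nrow(values); m <- ncol(values)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  if (m < 1L) stop("at least 1 component is required", call. = FALSE)
  subject_ids <- as.character(subject_ids %||% rownames(values) %||% paste0("S", seq_len(n)))
  component_labels <- as.character(component_labels %||% colnames(values) %||% paste0("C", seq_len(m)))
  if (length(subject_ids) != n)
    stop("subject_ids must have one entry per row", call. = FALSE)
  if (anyDuplicated(subject_ids))
    stop("subject_ids must be unique", call. = FALSE)
  if (length(component_labels) != m)
    stop("component_labels must have one entry per column", call. = FALSE)
  dimnames(values) <- list(subject_ids, component_labels)
  class(values) <- c("effect_matrix", class(values))
  values
}

#' @rdname effect_matrix
#' @param x an `effect_matrix`
#' @export
n_subjects <- function(x) nrow(x)

#' @rdname effect_matrix
#' @export
n_components <- function(x) ncol(x)

#' @export
print.effect_matrix <- function(x, ...) {
  cat(sprintf("effect_matrix: %d subjects x %d components\n", nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

as_effect_matrix <- function(x) {
  if (inherits(x, "effect_matrix")) x else effect_matrix(x)
}
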