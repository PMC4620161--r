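detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a long-format effect table
#'
#' Reads a delimited text table (comma- or tab-separated, auto-detected)
#' with one row per subject x within-subject cell, in the style of a
#' group-analysis data table: a `Subj` column, one or more within-subject
#' factor columns, a numeric value column, and any remaining columns taken
#' as between-subject variables (which must be constant within subject).
#'
#' The wide n x m effect matrix is assembled with a deterministic component
#' ordering: factor levels in order of first appearance, cells flattened
#' row-major over the declared `within` order (first factor slowest).
#' Subjects with missing cells are removed listwise with a warning;
#' duplicated (subject, cell) rows are an error.
#'
#' @param path file path.
#' @param within character vector naming the within-subject factor
#'   column(s).
#' @param value name of the value column (default `"Value"`).
#' @param subject name of the subject-ID column (default `"Subj"`).
#' @return list with `B` (an [effect_matrix()]) and `subject_table` (one
#'   row per retained subject: `Subj` plus the between-subject columns).
#' @seealso [write_effect_table()]
#' @export
read_effect_table <- function(path, within = "Component", value = "Value",
                              subject = "Subj") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  need <- c(subject, within, value)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("table lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(tab[[value]]))
  bad <- which(is.na(vals) & !is.na(tab[[value]]))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in data row %d", tab[[value]][bad[1]],
                 bad[1]), call. = FALSE)
  if (anyNA(vals))
    stop("missing values in the value column", call. = FALSE)

  levs <- lapply(tab[within], function(x) unique(x))
  # row-major flattening: first declared factor varies slowest
  grid <- expand.grid(rev(levs), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(levs)), drop = FALSE]
  names(grid) <- within
  cell_labels <- apply(grid, 1L, paste, collapse = "_")
  cell_of <- apply(tab[within], 1L, paste, collapse = "_")

  subj <- tab[[subject]]
  key <- paste(subj, cell_of, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicated (subject, cell) row: ",
         gsub("\r", " / ", d), call. = FALSE)
  }
  subjects <- unique(subj)
  wide <- matrix(NA_real_, length(subjects), length(cell_labels),
                 dimnames = list(subjects, cell_labels))
  wide[cbind(match(subj, subjects), match(cell_of, cell_labels))] <- vals
  incomplete <- rownames(wide)[rowSums(is.na(wide)) > 0L]
  if (length(incomplete)) {
    warning("dropping subject(s) with missing cells (listwise deletion): ",
            paste(incomplete, collapse = ", "), call. = FALSE)
    wide <- wide[!rownames(wide) %in% incomplete, , drop = FALSE]
    tab <- tab[!subj %in% incomplete, , drop = FALSE]
    subj <- tab[[subject]]
  }
  if (nrow(wide) < 2L)
    stop("fewer than 2 complete subjects remain", call. = FALSE)

  between_cols <- setdiff(names(tab), need)
  first <- !duplicated(subj)
  subject_table <- data.frame(Subj = subj[first], stringsAsFactors = FALSE)
  for (bc in between_cols) {
    consistent <- tapply(tab[[bc]], subj, function(v) length(unique(v)) == 1L)
    if (!all(consistent))
      stop(sprintf("between-subject variable '%s' varies within a subject", bc),
           call. = FALSE)
    v <- tab[[bc]][first]
    num <- suppressWarnings(as.numeric(v))
    subject_table[[bc]] <- if (!anyNA(num)) num else v
  }
  subject_table <- subject_table[match(rownames(wide), subject_table$Subj), ,
                                 drop = FALSE]
  rownames(subject_table) <- NULL
  list(B = effect_matrix(wide), subject_table = subject_table)
}

#' Write an effect matrix as a long-format table
#'
#' Inverse of [read_effect_table()]: one row per subject x component, with
#' any between-subject variables repeated per subject. Comma-separated when
#' the path ends in `.csv`, tab-separated otherwise.
#'
#' @param B an [effect_matrix()].
#' @param path output file.
#' @param subject_table optional per-subject table (a `Subj` column plus
#'   between-subject variables) merged into the output.
#' @param within name of the within-subject factor column.
#' @param value name of the value column.
#' @return the path, invisibly.
#' @export
write_effect_table <- function(B, path, subject_table = NULL,
                               within = "Component", value = "Value") {
  B <- as_effect_matrix(B)
  long <- data.frame(Subj = rep(rownames(B), each = ncol(B)),
                     stringsAsFactors = FALSE)
  if (!is.null(subject_table)) {
    idx <- match(long$Subj, subject_table$Subj)
    if (anyNA(idx)) stop("subject_table lacks some subjects of B", call. = FALSE)
    for (bc in setdiff(names(subject_table), "Subj"))
      long[[bc]] <- subject_table[[bc]][idx]
  }
  long[[within]] <- rep(colnames(B), times = nrow(B))
  # 17 significant digits so that read-back reproduces the doubles exactly
  long[[value]] <- sprintf("%.17g", as.vector(t(unclass(B))))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(long, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
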