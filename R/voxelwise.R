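#' Voxelwise application of the shape tests
#'
#' Runs the requested test battery at every in-mask voxel of a set of
#' per-subject NIfTI images, assembling the n x m effect matrix per voxel
#' from the manifest and applying exactly the same machinery as the
#' table mode ([run_shape_tests()]): identical per-voxel data give
#' identical statistics in both modes.
#'
#' The manifest has one row per (subject, within-subject cell): columns
#' `Subj`, `Cell`, `File`, `Volume` (1-based volume index within the file),
#' plus optional between-subject variables. All images must share grid
#' dimensions and orientation metadata; a mismatch is an error before any
#' computation. Voxels where the tests cannot be computed (all-zero or
#' otherwise degenerate data) carry a sentinel value of 0 in the statistic
#' images and 0 in the companion `computable` mask image.
#'
#' @param manifest data frame as above.
#' @param tests subset of `c("MVT", "XUV", "XMV", "AUC", "L2D", "LME")`.
#' @param spec optional [design_spec()] describing the between-subject
#'   model (built from the manifest's between-subject columns); default:
#'   intercept-only.
#' @param effect tested effect term (see [run_shape_tests()]); default the
#'   intercept, or the sole between-subject factor if exactly one is
#'   declared.
#' @param mask optional NIfTI path or logical/numeric array on the image
#'   grid; non-zero voxels are analyzed.
#' @param out_dir optional directory; when given, one NIfTI image per
#'   (method, quantity in F/Z) plus the `computable` mask is written there,
#'   with a plain-text sidecar listing the outputs.
#' @param correction sphericity correction for XUV.
#' @return (invisibly) a list with `arrays` (named list of 3D statistic
#'   arrays), `computable` (logical array), and `files` (written paths, if
#'   any).
#' @export
run_voxelwise <- function(manifest, tests = c("MVT", "XUV", "AUC"),
                          spec = NULL, effect = NULL, mask = NULL,
                          out_dir = NULL, correction = "GG") {
  req <- c("Subj", "Cell", "File", "Volume")
  miss <- setdiff(req, names(manifest))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  subjects <- unique(manifest$Subj)
  cells <- unique(manifest$Cell)
  n <- length(subjects); m <- length(cells)
  got <- table(factor(manifest$Subj, subjects), factor(manifest$Cell, cells))
  if (any(got != 1L))
    stop("every subject must contribute exactly one image per cell", call. = FALSE)

  files <- unique(manifest$File)
  imgs <- lapply(files, RNifti::readNifti)
  names(imgs) <- files
  dims <- lapply(imgs, function(im) dim(im)[1:3])
  xforms <- lapply(imgs, function(im) round(RNifti::xform(im), 6))
  if (length(files) > 1L) {
    same <- vapply(seq_along(imgs)[-1], function(i)
      identical(dims[[i]], dims[[1]]) && identical(xforms[[i]], xforms[[1]]), TRUE)
    if (!all(same))
      stop("grid mismatch: input images differ in dimensions or orientation",
           call. = FALSE)
  }
  grid <- dims[[1]]
  nvox <- prod(grid)

  mask_arr <- if (is.null(mask)) array(TRUE, grid) else {
    marr <- if (is.character(mask)) {
      mimg <- RNifti::readNifti(mask)
      if (!identical(dim(mimg)[1:3], grid))
        stop("grid mismatch: mask does not match the input images", call. = FALSE)
      as.array(mimg)
    } else mask
    if (!identical(dim(marr)[1:3], grid))
      stop("grid mismatch: mask does not match the input images", call. = FALSE)
    array(marr != 0, grid)
  }

  # n x m x v data block over in-mask voxels
  vox <- which(mask_arr)
  data_block <- array(NA_real_, c(n, m, length(vox)))
  for (r in seq_len(nrow(manifest))) {
    im <- imgs[[manifest$File[r]]]
    vol <- manifest$Volume[r]
    flat <- if (length(dim(im)) > 3L) as.vector(im[, , , vol]) else {
      if (vol != 1L) stop("volume index out of range for 3D image", call. = FALSE)
      as.vector(im)
    }
    data_block[match(manifest$Subj[r], subjects),
               match(manifest$Cell[r], cells), ] <- flat[vox]
  }

  subject_table <- manifest[!duplicated(manifest$Subj),
                            setdiff(names(manifest), c("Cell", "File", "Volume")),
                            drop = FALSE]
  subject_table <- subject_table[match(subjects, subject_table$Subj), , drop = FALSE]
  X <- if (is.null(spec)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
       else encode_between_design(spec, subject_table)
  if (is.null(effect) && !is.null(spec) && length(spec$between_factors) == 1L)
    effect <- names(spec$between_factors)

  stat_arrays <- list()
  for (t in tests) {
    stat_arrays[[paste0(t, "_F")]] <- array(0, grid)
    stat_arrays[[paste0(t, "_Z")]] <- array(0, grid)
  }
  computable <- array(FALSE, grid)
  for (v in seq_along(vox)) {
    B <- data_block[, , v, drop = FALSE][, , 1]
    res <- tryCatch(
      run_shape_tests(effect_matrix(B, subject_ids = subjects,
                                    component_labels = cells),
                      X, effect = effect, methods = tests,
                      correction = correction),
      error = function(e) NULL)
    if (is.null(res) || anyNA(res$statistic) || any(!is.finite(res$z))) next
    computable[vox[v]] <- TRUE
    for (k in seq_len(nrow(res))) {
      stat_arrays[[paste0(res$method[k], "_F")]][vox[v]] <- res$statistic[k]
      stat_arrays[[paste0(res$method[k], "_Z")]][vox[v]] <- res$z[k]
    }
  }

  written <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    template <- imgs[[1]]
    for (nm in names(stat_arrays)) {
      p <- file.path(out_dir, paste0(nm, ".nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(stat_arrays[[nm]], reference = template), p)
      written <- c(written, p)
    }
    p <- file.path(out_dir, "computable.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(computable), grid),
                                       reference = template), p)
    written <- c(written, p)
    sidecar <- file.path(out_dir, "outputs.txt")
    writeLines(c(sprintf("hdrshape voxelwise outputs (%d voxels analyzed)",
                         sum(computable)),
                 sprintf("effect: %s", effect %||% "(Intercept)"),
                 basename(written)), sidecar)
    written <- c(written, sidecar)
  }
  invisible(list(arrays = stat_arrays, computable = computable, files = written))
}
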