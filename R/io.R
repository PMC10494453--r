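#' Read and write volumes as NIfTI-1
#'
#' Volumes round-trip data, spacing and affine for the dtypes used; masks are
#' stored as unsigned 8-bit and stay binary on read.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return [read_volume()] returns an `aneu_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop_aneu(sprintf("cannot read volume: '%s' does not exist", path),
              "aneu_io_error")
  }
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop_aneu(sprintf("corrupt or unreadable NIfTI '%s': %s", path,
                      conditionMessage(e)), "aneu_io_error")
  })
  sp <- RNifti::pixdim(img)[1:3]
  new_volume(array(as.numeric(img), dim(img)[1:3]), sp)
}

#' @rdname read_volume
#' @param vol an `aneu_volume`.
#' @param mask store as unsigned 8-bit (for binary masks).
#' @export
write_volume <- function(vol, path, mask = FALSE) {
  sp <- voxel_spacing(vol)
  img <- RNifti::asNifti(array(if (mask) as.integer(vol) else as.numeric(vol),
                               dim(vol)))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path,
                     datatype = if (mask) "uint8" else "double")
  invisible(path)
}

case_schema <- c("id", "location", "size_mm", "height_mm", "neck_mm",
                 "dome_mm", "volume_mm3")

#' Read and write case tables
#'
#' The cohort CSV schema is `id, location, size_mm, height_mm, neck_mm,
#' dome_mm, volume_mm3[, coil_mm, predicted_mm]`; unknown extra columns are
#' preserved. `require_coil = TRUE` (training use) additionally demands the
#' `coil_mm` column.
#'
#' @param path CSV path.
#' @param require_coil demand the actual-coil column.
#' @return tibble of cases.
#' @export
read_cases <- function(path, require_coil = FALSE) {
  if (!file.exists(path)) {
    stop_aneu(sprintf("cannot read cases: '%s' does not exist", path),
              "aneu_io_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(case_schema, if (require_coil) "coil_mm")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop_aneu(sprintf("case table is missing required column(s): %s",
                      paste(missing, collapse = ", ")), "aneu_schema_error")
  }
  if (anyDuplicated(tab$id)) {
    stop_aneu("case ids must be unique", "aneu_schema_error")
  }
  tab
}

#' @rdname read_cases
#' @param table tibble of cases.
#' @export
write_cases <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Load a generated cohort from its manifest
#'
#' Reads back a cohort written by [generate_cohort()]: volumes, masks and the
#' morphometry/label table, in the same structure [simulate_cohort()] returns,
#' so a cohort on disk can feed [train_segmenter()] directly.
#'
#' @param manifest_path path to `manifest.json`.
#' @return list with `cases` and `table`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_aneu(sprintf("manifest '%s' does not exist", manifest_path),
              "aneu_io_error")
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  files <- man$files
  tab <- read_cases(man$csv)
  cases <- lapply(seq_len(nrow(files)), function(i) {
    pre <- read_volume(files$pre[i])
    post <- read_volume(files$post[i])
    list(pre = pre, post = post,
         subtracted = subtract_volumes(post, pre),
         truth = list(aneurysm_mask = read_volume(files$aneurysm[i]),
                      vessel_mask = read_volume(files$vessel[i])),
         spec = tibble::tibble(id = files$id[i],
                               with_aneurysm = files$with_aneurysm[i],
                               location = tab$location[match(files$id[i],
                                                             tab$id)]))
  })
  list(cases = cases, table = tab)
}
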