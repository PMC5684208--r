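#' @title File interchange helpers
#' @description Thin readers/writers for the pipeline's standard formats:
#'   NIfTI volumes for imaging, CSV for tracking/traces/spike times/feature
#'   tables, JSON for cluster reports, band-power tables and ground truth.
#' @name io
NULL

#' Write a 3-D volume (or CBV map) to NIfTI
#' @param vol 3-D array or `cbv_map`.
#' @param path Output file (`.nii` / `.nii.gz`).
#' @param pixdim Voxel size (mm, default `c(1, 1, 1)`).
#' @export
write_volume_nifti <- function(vol, path, pixdim = c(1, 1, 1)) {
  if (inherits(vol, "cbv_map")) vol <- vol$values
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D volume from NIfTI
#' @param path NIfTI file.
#' @return Numeric 3-D array.
#' @export
read_volume_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  storage.mode(arr) <- "double"
  arr
}

#' Read a tracking CSV (columns time, x, y)
#' @param path CSV file.
#' @export
read_tracking_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time", "x", "y") %in% names(df)))
  df
}

#' Write a data frame to CSV (no row names)
#' @param df Data frame.
#' @param path Output file.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cluster report as JSON
#' @param clusters A `cluster_set`.
#' @param path Output file.
#' @export
write_cluster_json <- function(clusters, path) {
  rep <- list(critical_size = clusters$critical_size,
              alpha = clusters$alpha, height_p = clusters$height_p,
              connectivity = clusters$connectivity,
              clusters = lapply(seq_along(clusters$sizes), function(i) {
                list(size = clusters$sizes[i], peak_t = clusters$peak_t[i],
                     voxels = as.integer(clusters$clusters[[i]]))
              }))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ground truth (or any list) as JSON
#' @param x List to serialize.
#' @param path Output file.
#' @export
write_ground_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
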