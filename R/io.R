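# NIfTI image I/O and model checkpoint plumbing.

#' Read / write a 2-D image as NIfTI
#'
#' Thin wrappers over RNifti preserving the pixel spacing; the stored array
#' round-trips bit-exactly (double precision).
#'
#' @param image numeric matrix.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param pixel_spacing pixel size in mm (scalar or length-2).
#' @export
write_image <- function(image, path, pixel_spacing = 4.0) {
  check_nifti_path(path)
  sp <- rep_len(pixel_spacing, 2)
  img <- structure(unclass(image), pixdim = sp)
  RNifti::writeNifti(RNifti::asNifti(img, datatype = "double"), path,
                     datatype = "double")
  invisible(path)
}

#' @rdname write_image
#' @return `read_image()` returns `list(image, spacing)`.
#' @export
read_image <- function(path) {
  check_nifti_path(path)
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop_format(sprintf(
                    "malformed NIfTI file %s: %s", path, conditionMessage(e))))
  list(image = unclass(as.array(img))[, , drop = FALSE],
       spacing = RNifti::pixdim(img)[1:2])
}

check_nifti_path <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop_format(sprintf("expected a .nii/.nii.gz path, got %s", path))
  }
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a flat binary array of doubles plus a JSON shape
#' manifest and the JSON network configuration.
#'
#' @param net a `fedasc_net`.
#' @param prefix path prefix; writes `<prefix>.bin`,
#'   `<prefix>_manifest.json`, `<prefix>_config.json`.
#' @export
save_network <- function(net, prefix) {
  flat <- flatten_params(net)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(flat$vector, con, size = 8)
  jsonlite::write_json(flat$manifest, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(unclass(net$config), paste0(prefix, "_config.json"),
                       auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname save_network
#' @export
load_network <- function(prefix) {
  cfg_path <- paste0(prefix, "_config.json")
  bin_path <- paste0(prefix, ".bin")
  if (!file.exists(cfg_path) || !file.exists(bin_path)) {
    stop_io(sprintf("missing checkpoint files for prefix %s", prefix))
  }
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  # JSON has no Inf literal; the unbounded gradient clip round-trips as text
  if (!is.null(cfg$grad_clip)) cfg$grad_clip <- as.numeric(cfg$grad_clip)
  config <- do.call(network_config, cfg)
  net <- build_network(config)
  n <- length(flatten_params(net)$vector)
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  vec <- readBin(con, "double", n = n, size = 8)
  if (length(vec) != n) stop_format("checkpoint length does not match config")
  unflatten_params(net, vec)
}
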