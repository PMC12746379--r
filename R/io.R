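#' Write / read a Z-spectral image stack as NIfTI + JSON sidecar
#'
#' NIfTI-1 has no spectral axis, so the frequency-offset schedule travels in
#' a JSON sidecar (`<path without .nii[.gz]>.json`) holding the offsets at
#' full precision, the control offset, the saturation power and any extra
#' metadata.
#'
#' @param stack 3-D (x, y, offset) or 4-D (x, y, z, offset) numeric array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param schedule An [offset_schedule()] matching the last array dimension.
#' @param power_uT Saturation power recorded in the sidecar.
#' @param meta Optional named list of extra sidecar fields.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, schedule, power_uT = NA_real_, meta = list()) {
  d <- dim(stack)
  stopifnot(length(d) %in% c(3, 4), inherits(schedule, "offset_schedule"))
  if (d[length(d)] != length(schedule))
    stop("last stack dimension does not match the schedule length")
  RNifti::writeNifti(RNifti::asNifti(stack, datatype = "double"), path)
  sidecar <- c(list(offsets_ppm = schedule$offsets_ppm,
                    control_ppm = schedule$control_ppm,
                    power_uT = power_uT), meta)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' @rdname write_stack
#' @return For `read_stack`: list with `stack`, `schedule`, `power_uT`, `meta`.
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing offsets metadata: sidecar file not found: ", sc)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  stack <- as.array(RNifti::readNifti(path))
  d <- dim(stack)
  if (d[length(d)] != length(side$offsets_ppm))
    stop("stack length does not match the sidecar offset schedule")
  schedule <- offset_schedule(side$offsets_ppm, side$control_ppm)
  meta <- side[setdiff(names(side), c("offsets_ppm", "control_ppm", "power_uT"))]
  list(stack = stack, schedule = schedule,
       power_uT = side$power_uT %||% NA_real_, meta = meta)
}

#' Save / load a trained denoiser
#'
#' The parameters go to an RDS file and the architecture/training settings to
#' a human-readable JSON sidecar next to it.
#'
#' @param model A `cest_denoiser`.
#' @param path Output `.rds` path.
#' @return `path` / the restored `cest_denoiser`.
#' @export
save_denoiser <- function(model, path) {
  stopifnot(inherits(model, "cest_denoiser"))
  saveRDS(model, path)
  cfg <- list(input_len = model$config$input_len,
              in_channels = model$config$in_channels,
              channels = model$config$channels,
              kernel = model$config$kernel,
              n_params = model$n_params,
              trained = model$trained,
              seed = model$seed)
  jsonlite::write_json(cfg, paste0(sub("\\.rds$", "", path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cest_denoiser"))
  model
}
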