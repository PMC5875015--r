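# Readers and writers for the package's on-disk interchange formats:
# per-channel 16-bit TIFFs, long-format profile CSVs, trace CSVs and JSON
# manifests.

#' Write a well image set as per-channel 16-bit TIFFs
#'
#' Files are named `<WELL>_<BF|GFP|RED>.tif` under `dir`.
#'
#' @param images A [well_image_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_well_images <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chans <- list(BF = images$brightfield, GFP = images$green)
  if (!is.null(images$red)) chans$RED <- images$red
  paths <- character(0)
  for (nm in names(chans)) {
    p <- file.path(dir, sprintf("%s_%s.tif", images$well_id, nm))
    # tiff expects [row, col] = [y, x] in [0, 1]
    tiff::writeTIFF(t(chans[[nm]]) / 65535, p, bits.per.sample = 16L,
                    compression = "none")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a well image set written by [write_well_images()]
#'
#' @param dir Directory holding the TIFFs.
#' @param well_id Well identifier used in the file names.
#' @param pixel_size µm per pixel to attach.
#' @return A [well_image_set()].
#' @export
read_well_images <- function(dir, well_id, pixel_size = 6.5) {
  rd <- function(nm) {
    p <- file.path(dir, sprintf("%s_%s.tif", well_id, nm))
    if (!file.exists(p)) return(NULL)
    m <- t(tiff::readTIFF(p)) * 65535
    storage.mode(m) <- "integer"
    m
  }
  bf <- rd("BF"); gr <- rd("GFP")
  if (is.null(bf) || is.null(gr))
    stop_input("missing BF/GFP TIFF for well ", well_id, " in ", dir)
  well_image_set(bf, gr, rd("RED"), pixel_size = pixel_size, well_id = well_id)
}

#' Write flow profiles to long-format CSV
#'
#' Columns: `object_id`, `channel` (`extinction`/`green`), `sample_index`,
#' `value`; sample spacing is recorded in a sidecar attribute column-free
#' header comment is avoided by storing it per row.
#'
#' @param profiles List of [flow_profile()] objects.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(object_id = i,
               channel = rep(c("extinction", "green"), each = length(p$green)),
               sample_index = rep(seq_along(p$green), 2),
               value = c(p$extinction, p$green),
               sample_spacing = p$sample_spacing)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read flow profiles from long-format CSV
#'
#' @param path CSV written by [write_profiles_csv()] (columns `object_id`,
#'   `channel`, `sample_index`, `value`, optional `sample_spacing`).
#' @return List of [flow_profile()] objects in `object_id` order.
#' @export
read_profiles_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$object_id), function(o) {
    o <- o[order(o$sample_index), ]
    flow_profile(o$value[o$channel == "extinction"],
                 o$value[o$channel == "green"],
                 sample_spacing = if ("sample_spacing" %in% names(o))
                   o$sample_spacing[1] else 3)
  })
}

#' Read luminescence traces from CSV
#'
#' @param path CSV with columns `time_min`, `lum` and optionally `animal`;
#'   one trace per animal.
#' @return Named list of [luc_trace()] objects.
#' @export
read_luc_traces <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"animal" %in% names(d)) d$animal <- "animal_1"
  lapply(split(d, d$animal), function(a) luc_trace(a$time_min, a$lum))
}

#' Write a run manifest as JSON
#'
#' Records the run id, the seed, per-stage configuration snapshots and the
#' written output files with their MD5 checksums, so a run can be audited and
#' reproduced.
#'
#' @param manifest A list (see [run_end_to_end()]).
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
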