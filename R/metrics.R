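#' Measure per-worm intensities and morphology
#'
#' For every accepted worm, computes the mean channel intensity over the worm
#' pixels (`int_worm_*`), the mean over its immediate-background ring
#' (`int_bkgd_*`), and their difference (`int_worm_minus_bkgd_*`), per
#' available channel. Worms with an empty background ring receive the plate
#' median of the other worms' ring intensities and are flagged
#' (`bkgd_fallback`). Intensities are means, so records compare across worm
#' sizes; summed variants (`total_*`) are also reported. The green channel is
#' additionally measured over the worm-minus-green-head region
#' (`int_worm_nohead_green`), the region used when a pharyngeal blob must not
#' inflate the body reporter signal. Morphology (area, skeleton length, major
#' axis, form factor, centroid) and the per-worm Green Head ID come from the
#' segmentation result.
#'
#' @param seg A `segmentation_result` from [segment_well_set()] /
#'   [link_targets()].
#' @param images The matching [well_image_set()].
#' @return A data.frame with one row per accepted worm (columns: `well_id`,
#'   `worm`, morphology, green — and red, when present — intensity fields,
#'   `green_head_id`, QC flags).
#' @export
measure_worms <- function(seg, images) {
  if (!identical(dim(seg$worm_labels), dim(images$green)))
    stop_input("segmentation and images must share dimensions")
  obj <- seg$objects
  n <- nrow(obj)
  ps <- images$pixel_size
  base <- data.frame(
    well_id = rep(images$well_id, n),
    worm = if (n) obj$label else integer(0),
    area_px = obj$area_px, area_um2 = obj$area_px * ps^2,
    length_um = obj$length_um, major_axis_um = obj$major_axis_um,
    form_factor = obj$form_factor,
    centroid_x = obj$centroid_x, centroid_y = obj$centroid_y,
    green_head_id = if (n) obj$green_head_id else integer(0),
    empty_ring = if (n) obj$empty_ring else logical(0),
    stringsAsFactors = FALSE)
  channels <- list(green = images$green)
  if (!is.null(images$red)) channels$red <- images$red
  for (ch_name in names(channels)) {
    ch <- channels[[ch_name]]
    iw <- ib <- tot <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      px <- which(seg$worm_labels == obj$label[k])
      iw[k] <- mean(ch[px])
      tot[k] <- sum(ch[px])
      ring <- seg$rings[[obj$label[k]]]
      if (length(ring)) ib[k] <- mean(ch[ring])
    }
    fallback <- is.na(ib)
    if (any(fallback) && any(!fallback))
      ib[fallback] <- stats::median(ib[!fallback])
    base[[paste0("int_worm_", ch_name)]] <- iw
    base[[paste0("int_bkgd_", ch_name)]] <- ib
    base[[paste0("int_worm_minus_bkgd_", ch_name)]] <- iw - ib
    base[[paste0("total_", ch_name)]] <- tot
    if (ch_name == "green") {
      inh <- rep(NA_real_, n)
      for (k in seq_len(n)) {
        px <- which(seg$worm_minus_head_labels == obj$label[k])
        if (length(px)) inh[k] <- mean(ch[px])
      }
      base$int_worm_nohead_green <- inh
      base$int_worm_nohead_minus_bkgd_green <- inh - ib
    }
    base$bkgd_fallback <- if (n) fallback else logical(0)
  }
  base
}

#' Summarize one well's worm records
#'
#' @param records A per-worm data.frame (from [measure_worms()] or the screen
#'   table generator).
#' @param measures Character vector of numeric columns to aggregate; defaults
#'   to every numeric measurement column present.
#' @return A one-row data.frame: `n` plus `<measure>_mean`, `<measure>_median`
#'   and `<measure>_cv` for each measure (NA when `n = 0`, CV NA when
#'   undefined).
#' @export
summarize_well <- function(records, measures = NULL) {
  if (is.null(measures)) {
    skip <- c("worm", "green_head_id", "centroid_x", "centroid_y")
    measures <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                        skip)
  }
  out <- data.frame(n = nrow(records))
  for (m in measures) {
    v <- records[[m]]
    out[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
    out[[paste0(m, "_median")]] <- if (length(v)) stats::median(v) else NA_real_
    mu <- out[[paste0(m, "_mean")]]
    out[[paste0(m, "_cv")]] <- if (length(v) >= 2 && !is.na(mu) && mu != 0)
      stats::sd(v) / mu else NA_real_
  }
  out
}
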