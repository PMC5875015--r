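#' Segmentation configuration
#'
#' Tunable parameters of the well-image segmentation protocol. The defaults
#' are calibrated on the package's synthetic wells (6.5 µm/px, 512 px frames)
#' and every threshold is exposed so users can re-tune them for their own
#' optics; morphological acceptance bounds follow the category list used for
#' whole-well worm screens (area, skeleton length, form factor, border
#' contact).
#'
#' @param well_edge_threshold Green intensity (a.u.) above which pixels are
#'   treated as well-edge autofluorescence.
#' @param min_ring_area Minimum pixel count for a detected edge ring; below
#'   this the well mask falls back to the full frame with a warning.
#' @param blur_sigma Gaussian sigma (px) of the local-illumination estimate
#'   used for brightfield contrast normalization.
#' @param dark_threshold Objects are pixels whose normalized brightfield
#'   (image / smoothed image) falls below this value.
#' @param min_candidate_area Specks below this pixel area are removed before
#'   object filtering.
#' @param area_range_px Accepted worm area range, px^2.
#' @param length_range_um Accepted skeleton length range, µm.
#' @param form_factor_max Maximum form factor `4*pi*A/P^2` (worms are
#'   elongated, so compact blobs such as filled bubbles exceed this).
#' @param drop_border Drop objects touching the image border.
#' @param head_area_px Green-head (pharynx) object area range, px^2.
#' @param head_intensity_mult Green-head threshold as a multiple of the median
#'   green intensity over all accepted worm pixels (scale-free); set
#'   `head_abs_threshold` for an absolute alternative.
#' @param head_abs_threshold Optional absolute green-head threshold (a.u.).
#' @param dilation_radius Background-ring dilation radius, px (>= 1): the
#'   width of the immediate-background band measured around each worm.
#' @param dilation_gap Guard gap, px: the ring starts this many pixels beyond
#'   the worm boundary, so boundary pixels the brightfield segmentation may
#'   have missed (and the bright halo around dark bodies) do not contaminate
#'   the background estimate.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(well_edge_threshold = 2000, min_ring_area = 500,
                       blur_sigma = 25, dark_threshold = 0.9,
                       min_candidate_area = 30,
                       area_range_px = c(500, 6000),
                       length_range_um = c(300, 1400),
                       form_factor_max = 0.5, drop_border = TRUE,
                       head_area_px = c(20, 600), head_intensity_mult = 4,
                       head_abs_threshold = NULL, dilation_radius = 5,
                       dilation_gap = 2) {
  if (dilation_radius < 1) stop_input("dilation_radius must be >= 1")
  if (diff(area_range_px) <= 0 || diff(length_range_um) <= 0 ||
      diff(head_area_px) <= 0)
    stop_input("acceptance ranges must be non-degenerate")
  structure(as.list(environment()), class = "seg_config")
}

largest_cc <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(NULL)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Segment the usable well interior from the green channel
#'
#' The bright well-edge autofluorescence ring is thresholded in the green
#' channel; the filled interior of the largest ring component, minus the ring
#' itself, becomes the well mask (a single connected region). If no ring is
#' found the full frame is returned with a warning.
#'
#' @param green Green-channel raster (matrix, 16-bit range).
#' @param cfg A [seg_config()].
#' @return Logical matrix marking the usable interior.
#' @export
segment_well <- function(green, cfg = seg_config()) {
  bright <- green >= cfg$well_edge_threshold
  ring <- largest_cc(bright)
  if (is.null(ring) || sum(ring) < cfg$min_ring_area) {
    warning("no well-edge ring detected; using full-frame well mask")
    return(matrix(TRUE, nrow(green), ncol(green)))
  }
  interior <- EBImage::fillHull(ring) & !ring
  keep <- largest_cc(interior)
  if (is.null(keep)) {
    warning("well-edge ring has no interior; using full-frame well mask")
    return(matrix(TRUE, nrow(green), ncol(green)))
  }
  keep
}

#' Segment worm candidates from the brightfield channel
#'
#' The brightfield image is contrast-normalized by dividing by a heavily
#' smoothed copy of itself (flattening uneven illumination), dark tube-shaped
#' objects are thresholded, the well mask is applied so well-edge artefacts
#' are subtracted, and sub-speck components are discarded. No morphological
#' acceptance filtering happens here; see [filter_objects()].
#'
#' @param brightfield Brightfield raster (matrix).
#' @param well_mask Logical matrix from [segment_well()].
#' @param cfg A [seg_config()].
#' @return Integer label matrix of candidate objects (0 = background).
#' @export
segment_worms <- function(brightfield, well_mask, cfg = seg_config()) {
  bfn <- brightfield / 65535
  # the smoothing kernel (2*ceil(3*sigma)+1 wide) must fit inside the frame
  sigma <- min(cfg$blur_sigma, floor((min(dim(bfn)) / 2 - 1) / 3))
  smooth <- EBImage::gblur(bfn, sigma = sigma)
  enhanced <- bfn / pmax(smooth, 1e-6)
  cand <- enhanced < cfg$dark_threshold & well_mask
  lab <- EBImage::bwlabel(cand)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < cfg$min_candidate_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_consecutive(lab)
  }
  storage.mode(lab) <- "integer"
  lab
}

relabel_consecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) return(lab)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

# Per-object morphology for a label image: area, perimeter, form factor,
# skeleton length, major axis, centroid, border contact.
object_morphology <- function(lab, pixel_size) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0)
    return(data.frame(label = integer(), area_px = numeric(),
                      perimeter_px = numeric(), form_factor = numeric(),
                      length_um = numeric(), major_axis_um = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      touches_border = logical()))
  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab)
  skel <- vapply(ids, function(k) object_skeleton_length(lab, k), numeric(1))
  border <- vapply(ids, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    any(w[, 1] %in% c(1L, nrow(lab))) || any(w[, 2] %in% c(1L, ncol(lab)))
  }, logical(1))
  area <- sh[, "s.area"]; per <- sh[, "s.perimeter"]
  data.frame(label = ids, area_px = area, perimeter_px = per,
             form_factor = pmin(4 * pi * area / pmax(per, 1)^2, 1),
             length_um = skel * pixel_size,
             major_axis_um = mo[, "m.majoraxis"] * pixel_size,
             centroid_x = mo[, "m.cx"], centroid_y = mo[, "m.cy"],
             touches_border = border, row.names = NULL)
}

#' Apply morphological acceptance criteria to candidate objects
#'
#' Removes unwanted objects — long fibres, air bubbles, overlapping worms —
#' using area, skeleton-length, form-factor and border rules. Excluded
#' objects are recorded with the first violated criterion (order: area below,
#' area above, length below, length above, form factor, border). Accepted
#' objects are relabelled consecutively from 1.
#'
#' @param candidates Candidate label matrix from [segment_worms()].
#' @param cfg A [seg_config()].
#' @param pixel_size µm per pixel.
#' @return List: `labels` (accepted label matrix), `objects` (data.frame of
#'   accepted-object morphology, one row per accepted label), `excluded`
#'   (data.frame: original label, reason, morphology).
#' @export
filter_objects <- function(candidates, cfg = seg_config(), pixel_size = 6.5) {
  morph <- object_morphology(candidates, pixel_size)
  reason <- rep(NA_character_, nrow(morph))
  reason[is.na(reason) & morph$area_px < cfg$area_range_px[1]] <- "area_below"
  reason[is.na(reason) & morph$area_px > cfg$area_range_px[2]] <- "area_above"
  reason[is.na(reason) & morph$length_um < cfg$length_range_um[1]] <- "length_below"
  reason[is.na(reason) & morph$length_um > cfg$length_range_um[2]] <- "length_above"
  reason[is.na(reason) & morph$form_factor > cfg$form_factor_max] <- "form_factor"
  if (cfg$drop_border)
    reason[is.na(reason) & morph$touches_border] <- "border"
  keep <- is.na(reason)
  lab <- candidates
  if (any(!keep)) lab[lab %in% morph$label[!keep]] <- 0L
  lab <- relabel_consecutive(lab)
  objects <- morph[keep, , drop = FALSE]
  if (nrow(objects)) objects$label <- seq_len(nrow(objects))
  excluded <- cbind(morph[!keep, , drop = FALSE],
                    reason = reason[!keep])
  list(labels = lab, objects = objects,
       excluded = excluded[, c("label", "reason", "area_px", "length_um",
                               "form_factor", "touches_border")])
}

#' Detect pharyngeal GFP objects (green heads) and link them to worms
#'
#' Compact, very bright green objects are segmented by thresholding at a
#' multiple of the median green intensity over all accepted worm pixels,
#' filtered by area, and linked to the worm they overlap by at least one
#' pixel. Head pixels are clipped to their linked worm so head regions are
#' always subsets of worm regions. Candidate heads overlapping no worm are
#' dropped with a warning.
#'
#' @param green Green-channel raster.
#' @param worm_labels Accepted worm label matrix from [filter_objects()].
#' @param cfg A [seg_config()].
#' @param well_mask Optional logical matrix restricting the search (excludes
#'   the bright well-edge ring).
#' @return List: `labels` (green-head label matrix, consecutive), `head_worm`
#'   (integer vector mapping head label -> worm label), `head_count` (integer
#'   vector indexed by worm label: the per-worm Green Head ID).
#' @export
detect_green_heads <- function(green, worm_labels, cfg = seg_config(),
                               well_mask = NULL) {
  n_worms <- max(worm_labels)
  empty <- list(labels = matrix(0L, nrow(green), ncol(green)),
                head_worm = integer(0),
                head_count = integer(max(n_worms, 0)))
  body_px <- green[worm_labels > 0]
  if (length(body_px) == 0) return(empty)
  thr <- cfg$head_abs_threshold %||%
    (cfg$head_intensity_mult * stats::median(body_px))
  cand <- green >= thr
  if (!is.null(well_mask)) cand <- cand & well_mask
  lab <- EBImage::bwlabel(cand)
  if (max(lab) == 0) return(empty)
  sizes <- tabulate(lab[lab > 0])
  out <- matrix(0L, nrow(green), ncol(green))
  head_worm <- integer(0)
  for (k in which(sizes >= cfg$head_area_px[1] & sizes <= cfg$head_area_px[2])) {
    px <- which(lab == k)
    over <- worm_labels[px]
    over <- over[over > 0]
    if (length(over) == 0) {
      warning("green-head candidate overlaps no worm; dropped")
      next
    }
    worm <- as.integer(names(which.max(table(over))))
    linked <- px[worm_labels[px] == worm]   # clip to the linked worm
    head_worm <- c(head_worm, worm)
    out[linked] <- length(head_worm)
  }
  list(labels = out, head_worm = head_worm,
       head_count = tabulate(head_worm, nbins = n_worms))
}

#' Dilate worms to obtain per-worm immediate-background rings
#'
#' Each accepted worm is dilated by a disc; its background ring is the dilated
#' region minus the worm itself, minus every other worm's pixels, and minus
#' everything outside the well mask. A small guard gap (`dilation_gap`) is
#' left between the worm boundary and the ring so edge pixels and the
#' brightfield halo do not leak into the background estimate. Rings can come
#' out empty for tightly packed worms; these are flagged.
#'
#' @param worm_labels Accepted worm label matrix.
#' @param cfg A [seg_config()].
#' @param well_mask Logical matrix of the usable well interior.
#' @return List: `rings` (list of linear pixel-index vectors, one per worm),
#'   `dilated_labels` (label matrix of worm+ring regions, earlier labels win
#'   where dilations overlap), `empty_ring` (logical per worm).
#' @export
dilate_background <- function(worm_labels, cfg = seg_config(),
                              well_mask = NULL) {
  n <- max(worm_labels)
  nx <- nrow(worm_labels); ny <- ncol(worm_labels)
  rings <- vector("list", n)
  dil_lab <- matrix(0L, nx, ny)
  empty_ring <- logical(n)
  gap <- cfg$dilation_gap
  r <- gap + cfg$dilation_radius
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  brush_gap <- if (gap >= 1) EBImage::makeBrush(2 * gap + 1, shape = "disc")
  for (k in seq_len(n)) {
    w <- which(worm_labels == k, arr.ind = TRUE)
    xr <- max(1L, min(w[, 1]) - r):min(nx, max(w[, 1]) + r)
    yr <- max(1L, min(w[, 2]) - r):min(ny, max(w[, 2]) + r)
    crop <- worm_labels[xr, yr, drop = FALSE]
    dil <- EBImage::dilate(crop == k, brush)
    ring_crop <- dil & crop == 0
    if (gap >= 1) ring_crop <- ring_crop & !EBImage::dilate(crop == k, brush_gap)
    if (!is.null(well_mask)) ring_crop <- ring_crop & well_mask[xr, yr]
    rel <- which(ring_crop)
    gx <- xr[(rel - 1L) %% length(xr) + 1L]
    gy <- yr[(rel - 1L) %/% length(xr) + 1L]
    idx <- gx + (gy - 1L) * nx
    rings[[k]] <- idx
    empty_ring[k] <- length(idx) == 0
    relall <- which(dil)
    gxa <- xr[(relall - 1L) %% length(xr) + 1L]
    gya <- yr[(relall - 1L) %/% length(xr) + 1L]
    idxa <- gxa + (gya - 1L) * nx
    newpx <- idxa[dil_lab[idxa] == 0L]
    dil_lab[newpx] <- k
  }
  list(rings = rings, dilated_labels = dil_lab, empty_ring = empty_ring)
}

#' Link worm, dilated-background and green-head targets into one result
#'
#' Composes the per-worm measurement regions of the protocol: the worm mask,
#' the dilated-worm background ring, and the worm-minus-green-head region.
#' Linkage between a head and a worm requires at least one pixel of overlap
#' (enforced upstream in [detect_green_heads()]).
#'
#' @param well_mask Logical well-interior matrix.
#' @param worms Output of [filter_objects()].
#' @param heads Output of [detect_green_heads()].
#' @param bg Output of [dilate_background()].
#' @param pixel_size µm per pixel.
#' @return An object of class `segmentation_result` with fields `well_mask`,
#'   `worm_labels`, `objects` (per-worm table incl. `green_head_id` and
#'   `empty_ring`), `excluded`, `head_labels`, `head_worm`, `rings`,
#'   `dilated_labels`, `worm_minus_head_labels`, `pixel_size`.
#' @export
link_targets <- function(well_mask, worms, heads, bg, pixel_size = 6.5) {
  wmh <- worms$labels
  wmh[heads$labels > 0] <- 0L
  objects <- worms$objects
  if (nrow(objects)) {
    objects$green_head_id <- heads$head_count[objects$label]
    objects$empty_ring <- bg$empty_ring[objects$label]
  }
  structure(list(well_mask = well_mask, worm_labels = worms$labels,
                 objects = objects, excluded = worms$excluded,
                 head_labels = heads$labels, head_worm = heads$head_worm,
                 rings = bg$rings, dilated_labels = bg$dilated_labels,
                 worm_minus_head_labels = wmh, pixel_size = pixel_size),
            class = "segmentation_result")
}

#' Run the full segmentation protocol on one well
#'
#' Convenience wrapper: well mask from the green channel, worm candidates
#' from enhanced brightfield, morphological filtering, green-head detection,
#' background dilation and target linking.
#'
#' @param images A [well_image_set()].
#' @param cfg A [seg_config()].
#' @return A `segmentation_result` (see [link_targets()]).
#' @export
segment_well_set <- function(images, cfg = seg_config()) {
  wm <- segment_well(images$green, cfg)
  cand <- segment_worms(images$brightfield, wm, cfg)
  worms <- filter_objects(cand, cfg, pixel_size = images$pixel_size)
  heads <- detect_green_heads(images$green, worms$labels, cfg, well_mask = wm)
  bg <- dilate_background(worms$labels, cfg, well_mask = wm)
  link_targets(wm, worms, heads, bg, pixel_size = images$pixel_size)
}
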