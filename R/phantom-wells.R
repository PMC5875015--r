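#' Well image set container
#'
#' Registered per-channel rasters of one well from a whole-well 2x-objective
#' acquisition: brightfield, green (GFP) and optionally red, all sharing
#' dimensions, stored as integer matrices in the 16-bit range, plus the pixel
#' scale in micrometres per pixel.
#'
#' @param brightfield,green,red Integer matrices in `[0, 65535]`; `red` may be
#'   `NULL`.
#' @param pixel_size µm per pixel (> 0).
#' @param well_id Well identifier, e.g. `"A01"`.
#' @return An object of class `well_image_set`.
#' @export
well_image_set <- function(brightfield, green, red = NULL, pixel_size = 6.5,
                           well_id = "A01") {
  dims <- dim(brightfield)
  if (!identical(dim(green), dims) || (!is.null(red) && !identical(dim(red), dims)))
    stop_input("all channels must share identical dimensions")
  rng <- range(brightfield, green, if (!is.null(red)) red else 0)
  if (rng[1] < 0 || rng[2] > 65535) stop_input("pixel values must lie in [0, 65535]")
  if (pixel_size <= 0) stop_input("pixel_size must be > 0")
  structure(list(brightfield = brightfield, green = green, red = red,
                 pixel_size = pixel_size, well_id = well_id),
            class = "well_image_set")
}

#' @export
print.well_image_set <- function(x, ...) {
  cat(sprintf("<well_image_set> %s: %dx%d px @ %.2f um/px, channels: %s\n",
              x$well_id, nrow(x$brightfield), ncol(x$brightfield), x$pixel_size,
              paste(c("BF", "GFP", if (!is.null(x$red)) "RED"), collapse = "/")))
  invisible(x)
}

# Smooth random-walk midline: unit-pixel steps with heading interpolated
# through a handful of control headings, so the path is arc-length
# parameterized by construction. Returns an n x 2 matrix of (x, y) in pixels.
worm_midline <- function(length_px, start, heading0, n_ctrl = 5,
                         curl_sd = 0.6) {
  n <- max(8L, round(length_px))
  ctrl <- cumsum(c(heading0, stats::rnorm(n_ctrl - 1, 0, curl_sd)))
  heading <- stats::spline(seq(0, 1, length.out = n_ctrl), ctrl,
                           xout = seq(0, 1, length.out = n))$y
  cbind(start[1] + cumsum(cos(heading)) - cos(heading[1]),
        start[2] + cumsum(sin(heading)) - sin(heading[1]))
}

# Rasterize one tube-shaped body: distance from each pixel in the bounding
# box to the midline, against a tapered half-width profile. Returns pixel
# linear indices, signed depths and the nearest midline arc position.
rasterize_tube <- function(mid, half_width_px, dims, taper = TRUE) {
  n <- nrow(mid)
  t <- (seq_len(n) - 0.5) / n
  hw <- if (taper) half_width_px * pmax(sqrt(pmax(1 - (2 * t - 1)^2, 0)), 0.25)
        else rep(half_width_px, n)
  pad <- ceiling(max(hw)) + 2L
  xr <- max(1L, floor(min(mid[, 1])) - pad):min(dims[1], ceiling(max(mid[, 1])) + pad)
  yr <- max(1L, floor(min(mid[, 2])) - pad):min(dims[2], ceiling(max(mid[, 2])) + pad)
  px <- as.matrix(expand.grid(x = xr, y = yr))
  d2 <- outer(px[, 1], mid[, 1], "-")^2 + outer(px[, 2], mid[, 2], "-")^2
  j <- max.col(-d2)
  d <- sqrt(d2[cbind(seq_len(nrow(px)), j)])
  depth <- hw[j] - d   # > 0 inside the body
  keep <- depth > -3
  list(idx = px[keep, 1] + (px[keep, 2] - 1L) * dims[1],
       depth = depth[keep], arc = t[j[keep]], hw = hw[j[keep]])
}

place_disc <- function(center, radius, dims) {
  xr <- max(1L, floor(center[1] - radius)):min(dims[1], ceiling(center[1] + radius))
  yr <- max(1L, floor(center[2] - radius)):min(dims[2], ceiling(center[2] + radius))
  px <- as.matrix(expand.grid(x = xr, y = yr))
  d <- sqrt((px[, 1] - center[1])^2 + (px[, 2] - center[2])^2)
  list(idx = px[, 1] + (px[, 2] - 1L) * dims[1], d = d)
}

#' Generate a synthetic whole-well image set with ground truth
#'
#' Renders one well as seen through a 2x objective: brightfield shows worms as
#' dark curved tubes (with a faint bright halo) on a bright, evenly lit field;
#' the green channel shows a bright well-edge autofluorescence ring, uniform
#' body GFP for homozygotes, and for balancer heterozygotes a near-baseline
#' body plus a compact, very bright two-lobed anterior (pharyngeal) blob.
#' Optional artifacts reproduce the three classes that segmentation must
#' reject: long thin fibres, air bubbles (dark rims in brightfield) and
#' overlapping worm pairs. A linear background gradient can be applied to the
#' green channel.
#'
#' Worm bodies are painted with a hard mask at constant intensity so the
#' ground-truth label image reads back the true body GFP exactly (plus local
#' background) when `noise_cv = 0`.
#'
#' @param n_hom,n_het Numbers of homozygote / heterozygote worms.
#' @param artifacts List with counts `fibres`, `bubbles`, `overlaps`
#'   (an overlap places a crossing worm pair, both flagged as artifacts).
#' @param background List: `base` (green background a.u., default 100) and
#'   `gradient` length-2 (a.u. change across the full image in x and y).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param dims Image dimensions in pixels.
#' @param pixel_size µm per pixel (default 6.5 for a 2x objective).
#' @param body_gfp_mean Mean homozygote body GFP (a.u.); per-worm values are
#'   drawn lognormally with CV `body_gfp_cv` around it.
#' @param body_gfp_cv Between-worm CV of body GFP.
#' @param het_body_gfp Heterozygote body GFP level (a.u., near baseline).
#' @param pharynx_gfp Heterozygote pharyngeal blob intensity (a.u.).
#' @param red_level Per-worm red channel level (a.u.); 0 omits the red
#'   channel.
#' @param worm_length_um Length-2 range of body lengths (µm).
#' @param half_width_um Maximal body half-width (µm).
#' @param ring_frac Length-2 inner/outer well-ring radius as a fraction of the
#'   image half-width.
#' @param ring_level Green intensity of the well-edge ring (a.u.).
#' @param bf_field Brightfield field level (a.u.).
#' @param noise_cv Multiplicative pixel noise CV applied to both channels.
#' @param well_id Well identifier.
#' @param max_tries Placement retries per worm before a placement-failure
#'   error.
#' @return A list with `images` ([well_image_set()]) and `truth`
#'   (class `phantom_truth`: `label_image`, `worms` data.frame with genotype,
#'   true intensities, length and artifact flag, and `artifacts` spec list).
#' @export
generate_well_image <- function(n_hom, n_het,
                                artifacts = list(fibres = 0, bubbles = 0, overlaps = 0),
                                background = list(base = 100, gradient = c(0, 0)),
                                seed = 1, dims = c(512, 512), pixel_size = 6.5,
                                body_gfp_mean = 300, body_gfp_cv = 0.15,
                                het_body_gfp = 40, pharynx_gfp = 3000,
                                red_level = 0,
                                worm_length_um = c(850, 1050),
                                half_width_um = 32,
                                ring_frac = c(0.92, 0.99), ring_level = 6000,
                                bf_field = 30000, noise_cv = 0,
                                well_id = "A01", max_tries = 60) {
  if (n_hom < 0 || n_het < 0) stop_input("counts must be >= 0")
  set.seed(seed)
  nx <- dims[1]; ny <- dims[2]
  half <- min(nx, ny) / 2
  center <- c((nx + 1) / 2, (ny + 1) / 2)
  n_fib <- artifacts$fibres %||% 0
  n_bub <- artifacts$bubbles %||% 0
  n_ovl <- artifacts$overlaps %||% 0

  # base rasters (double precision until the final quantization)
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  r <- sqrt((xg - center[1])^2 + (yg - center[2])^2)
  grad <- background$gradient %||% c(0, 0)
  green <- (background$base %||% 100) + grad[1] * (xg - 1) / (nx - 1) +
    grad[2] * (yg - 1) / (ny - 1)
  bf <- matrix(bf_field, nx, ny)
  ring <- r >= ring_frac[1] * half & r <= ring_frac[2] * half
  outside <- r > ring_frac[2] * half
  green[ring] <- ring_level
  green[outside] <- 0.2 * (background$base %||% 100)
  bf[ring] <- bf_field * 0.8
  bf[outside] <- bf_field * 0.3

  label <- matrix(0L, nx, ny)
  occupied <- matrix(FALSE, nx, ny)
  use_red <- red_level > 0
  red <- if (use_red) matrix(10, nx, ny) else NULL

  inner_r <- ring_frac[1] * half
  hw_px <- half_width_um / pixel_size

  genotypes <- c(rep("homozygote", n_hom), rep("heterozygote", n_het),
                 rep(if (n_ovl > 0) c("homozygote"), 2 * n_ovl))
  artifact_flag <- c(rep(FALSE, n_hom + n_het), rep(TRUE, 2 * n_ovl))
  worms <- list(); art_spec <- list()
  cross_mid <- NULL  # midline of the first worm of the current overlap pair

  for (k in seq_along(genotypes)) {
    len_um <- stats::runif(1, worm_length_um[1], worm_length_um[2])
    len_px <- len_um / pixel_size
    is_second_of_pair <- artifact_flag[k] && (k - (n_hom + n_het)) %% 2 == 0
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (is_second_of_pair && !is.null(cross_mid)) {
        # start on one side of the partner's midpoint, heading across it
        mpt <- cross_mid[round(nrow(cross_mid) / 2), ]
        ang <- stats::runif(1, 0, 2 * pi)
        start <- mpt - 0.4 * len_px * c(cos(ang), sin(ang))
        mid <- worm_midline(len_px, start, ang, curl_sd = 0.3)
      } else {
        rho <- sqrt(stats::runif(1)) * 0.7 * inner_r
        th <- stats::runif(1, 0, 2 * pi)
        start <- center + rho * c(cos(th), sin(th))
        mid <- worm_midline(len_px, start, stats::runif(1, 0, 2 * pi))
      }
      rr <- sqrt((mid[, 1] - center[1])^2 + (mid[, 2] - center[2])^2)
      if (max(rr) > inner_r - hw_px - 3) next
      tube <- rasterize_tube(mid, hw_px, dims)
      core <- tube$idx[tube$depth > 0]
      clear <- if (is_second_of_pair) {
        # the pair must overlap each other but no third worm
        hit <- label[core]
        all(hit %in% c(0L, k - 1L)) && any(hit == k - 1L)
      } else !any(occupied[core])
      if (clear) {
        geno <- genotypes[k]
        body <- if (geno == "homozygote")
          rlnorm_mean_cv(1, body_gfp_mean, body_gfp_cv) else het_body_gfp
        # brightfield: soft dark core + faint halo
        soft <- pmin(pmax(tube$depth / 1.5, 0), 1)
        bf[tube$idx] <- bf[tube$idx] * (1 - 0.45 * soft)
        halo <- tube$depth <= 0 & tube$depth > -2
        bf[tube$idx[halo]] <- pmin(bf[tube$idx[halo]] * 1.08, 65535)
        # green body: hard mask, constant level (exact truth read-back)
        green[core] <- green[core] + body
        pharynx <- 0
        if (geno == "heterozygote") {
          pharynx <- pharynx_gfp
          n <- nrow(mid)
          for (lobe in list(c(0.06, 0.8), c(0.14, 0.6))) {
            ctr <- mid[max(1L, round(lobe[1] * n)), ]
            disc <- place_disc(ctr, lobe[2] * hw_px, dims)
            inside <- disc$idx[disc$d <= lobe[2] * hw_px]
            green[inside] <- green[inside] + pharynx_gfp
          }
        }
        if (use_red) red[core] <- red[core] + red_level
        newpx <- core[label[core] == 0L]
        label[newpx] <- k
        occupied[tube$idx] <- TRUE
        worms[[k]] <- data.frame(worm = k, genotype = geno,
                                 body_gfp = body, pharynx_gfp = pharynx,
                                 length_um = len_um, artifact = artifact_flag[k],
                                 stringsAsFactors = FALSE)
        if (artifact_flag[k] && !is_second_of_pair) cross_mid <- mid
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_input("placement failure: could not place worm ", k,
                 " without mandatory overlap")
  }

  # fibres: long (>= 10:1 aspect), thin, dark in brightfield; placed clear of
  # worms so artifact rejection can be tested independently of clumping
  for (f in seq_len(n_fib)) {
    for (try in seq_len(max_tries)) {
      len_um <- stats::runif(1, 500, 900)
      ang <- stats::runif(1, 0, 2 * pi)
      rho <- sqrt(stats::runif(1)) * 0.5 * inner_r
      th <- stats::runif(1, 0, 2 * pi)
      start <- center + rho * c(cos(th), sin(th))
      n <- round(len_um / pixel_size)
      mid <- cbind(start[1] + cumsum(rep(cos(ang), n)),
                   start[2] + cumsum(rep(sin(ang), n)))
      rr <- sqrt((mid[, 1] - center[1])^2 + (mid[, 2] - center[2])^2)
      mid <- mid[rr < inner_r - 3, , drop = FALSE]
      if (nrow(mid) < 10) next
      tube <- rasterize_tube(mid, 1, dims, taper = FALSE)
      core <- tube$idx[tube$depth > -0.2]
      if (any(occupied[core])) next
      bf[core] <- bf[core] * 0.5
      occupied[core] <- TRUE
      art_spec[[length(art_spec) + 1]] <-
        list(type = "fibre", length_um = nrow(mid) * pixel_size, angle = ang)
      break
    }
  }
  # bubbles: dark circular rims
  for (b in seq_len(n_bub)) {
    for (try in seq_len(max_tries)) {
      rad <- stats::runif(1, 130, 180) / pixel_size
      rho <- sqrt(stats::runif(1)) * 0.55 * inner_r
      th <- stats::runif(1, 0, 2 * pi)
      ctr <- center + rho * c(cos(th), sin(th))
      disc <- place_disc(ctr, rad + 3, dims)
      rim <- disc$idx[abs(disc$d - rad) <= 1.2]
      if (any(occupied[rim])) next
      bf[rim] <- bf[rim] * 0.5
      occupied[rim] <- TRUE
      art_spec[[length(art_spec) + 1]] <-
        list(type = "bubble", radius_um = rad * pixel_size)
      break
    }
  }
  if (n_ovl > 0)
    art_spec[[length(art_spec) + 1]] <- list(type = "overlap", pairs = n_ovl)

  if (noise_cv > 0) {
    green[] <- mult_noise(as.vector(green), noise_cv)
    bf[] <- mult_noise(as.vector(bf), noise_cv)
  }
  quant <- function(m) { m <- round(m); m[m < 0] <- 0; m[m > 65535] <- 65535
    storage.mode(m) <- "integer"; m }
  images <- well_image_set(quant(bf), quant(green),
                           if (use_red) quant(red) else NULL,
                           pixel_size = pixel_size, well_id = well_id)
  worm_tab <- if (length(worms)) do.call(rbind, worms) else
    data.frame(worm = integer(), genotype = character(), body_gfp = numeric(),
               pharynx_gfp = numeric(), length_um = numeric(),
               artifact = logical(), stringsAsFactors = FALSE)
  truth <- structure(list(label_image = label, worms = worm_tab,
                          artifacts = art_spec, ring_frac = ring_frac,
                          background = background, pixel_size = pixel_size),
                     class = "phantom_truth")
  list(images = images, truth = truth)
}
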