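#' Construct an axial flow profile
#'
#' A flow profile is the list of successive point measurements a large-particle
#' flow cytometer records along one object: an extinction (optical density)
#' series and a green fluorescence series of equal length, sampled at a fixed
#' axial spacing.
#'
#' @param extinction Numeric vector of extinction point measurements (a.u.,
#'   non-negative).
#' @param green Numeric vector of green fluorescence point measurements
#'   (a.u., non-negative), same length as `extinction`.
#' @param sample_spacing Axial distance between successive samples, in
#'   micrometres per sample.
#' @return An object of class `flow_profile`.
#' @export
flow_profile <- function(extinction, green, sample_spacing = 3) {
  if (length(extinction) != length(green))
    stop_input("extinction and green series must have equal length")
  if (length(green) < 1) stop_input("profile must contain at least one sample")
  if (any(extinction < 0) || any(green < 0))
    stop_input("profile values must be non-negative")
  if (sample_spacing <= 0) stop_input("sample_spacing must be > 0")
  structure(list(extinction = as.numeric(extinction),
                 green = as.numeric(green),
                 sample_spacing = sample_spacing),
            class = "flow_profile")
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("<flow_profile> %d samples @ %.1f um/sample, ExtPH=%.0f, greenPH=%.0f\n",
              length(x$green), x$sample_spacing, max(x$extinction), max(x$green)))
  invisible(x)
}

# Symmetric elliptical envelope over n samples, floored so the object has no
# zero-signal interior samples.
taper_envelope <- function(n, floor = 0.05) {
  t <- (seq_len(n) - 0.5) / n
  pmax(sqrt(pmax(1 - (2 * t - 1)^2, 0)), floor)
}

#' Generate synthetic axial flow profiles with ground truth
#'
#' Emulates the three object classes a sorter sees when processing a balanced
#' mutant population at the L2 stage:
#'
#' * **homozygote** — body-wide stress-reporter GFP: a broad green plateau
#'   (peak 2,000–4,000 a.u.) spanning most of a ~400–480 µm body, i.e. well
#'   over 120 samples above the 700 a.u. floor at 3 µm/sample;
#' * **heterozygote** — balancer carrier: body green near baseline plus two
#'   narrow, very bright pharyngeal lobes (15,000–30,000 a.u.) near the
#'   anterior, so the green peak height exceeds 10,000 while the
#'   above-threshold width stays far below 120 samples;
#' * **debris** — short objects (20–80 µm) with weak green and a short
#'   extinction extent.
#'
#' Noise is multiplicative lognormal per sample with the given coefficient of
#' variation; `noise_cv = 0` yields noiseless profiles. Identical arguments and
#' seed give bit-identical output.
#'
#' @param n_hom,n_het,n_debris Object counts (non-negative integers).
#' @param noise_cv Per-sample multiplicative noise CV (>= 0).
#' @param seed Integer seed.
#' @param sample_spacing Axial sampling interval, µm/sample (default 3, so an
#'   L2 body of ~400 µm spans ~130 samples).
#' @return A list with `profiles` (list of [flow_profile()]) and `truth`
#'   (data.frame with `object_id` and `class` in
#'   `homozygote`/`heterozygote`/`debris`).
#' @export
generate_flow_profiles <- function(n_hom, n_het, n_debris = 0, noise_cv = 0,
                                   seed = 1, sample_spacing = 3) {
  if (any(c(n_hom, n_het, n_debris) < 0)) stop_input("counts must be >= 0")
  if (noise_cv < 0) stop_input("noise_cv must be >= 0")
  set.seed(seed)
  classes <- rep(c("homozygote", "heterozygote", "debris"),
                 times = c(n_hom, n_het, n_debris))
  profiles <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    if (cl == "debris") {
      len_um <- stats::runif(1, 20, 80)
      n <- max(3L, round(len_um / sample_spacing))
      env <- taper_envelope(n)
      ext <- stats::runif(1, 2000, 9000) * env
      grn <- stats::runif(1, 0, 300) * env
    } else {
      len_um <- stats::runif(1, 400, 480)
      n <- round(len_um / sample_spacing)
      env <- taper_envelope(n)
      ext <- stats::runif(1, 12000, 25000) * env^0.5
      if (cl == "homozygote") {
        grn <- stats::runif(1, 2000, 4000) * env^0.3
      } else {
        grn <- stats::runif(1, 80, 200) * env^0.3
        # two pharyngeal lobes near the anterior end
        pk <- stats::runif(1, 15000, 30000)
        centers <- round(c(0.08, 0.16) * n)
        sigma <- 4 / sample_spacing  # ~4 um lobe half-width
        idx <- seq_len(n)
        grn <- grn + pk * (exp(-(idx - centers[1])^2 / (2 * sigma^2)) +
                           0.8 * exp(-(idx - centers[2])^2 / (2 * sigma^2)))
      }
    }
    profiles[[i]] <- flow_profile(mult_noise(ext, noise_cv),
                                  mult_noise(grn, noise_cv),
                                  sample_spacing)
  }
  list(profiles = profiles,
       truth = data.frame(object_id = seq_along(classes), class = classes,
                          stringsAsFactors = FALSE))
}
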