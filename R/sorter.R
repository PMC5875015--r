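#' Gating configuration for profile-based sorting
#'
#' Holds the extinction gate (a closed rectangle in peak-height / peak-width
#' space that selects worm-sized objects and removes debris) and the green
#' Profiler rule that accepts body-GFP homozygotes: green peak height within
#' `[green_ph_lo, green_ph_hi]` (defaults 700 and 10,000 a.u.) and integrated
#' above-floor width strictly greater than `green_pw_min` samples (default
#' 120). The pharyngeal-GFP signal of balancer heterozygotes is brighter than
#' the body reporter, so it fails the upper peak-height bound, and when dimmer
#' it is still much narrower than a worm body, failing the width criterion.
#'
#' @param ext_ph Length-2 numeric, closed extinction peak-height gate (a.u.).
#' @param ext_pw Length-2 numeric, closed extinction peak-width gate (samples).
#' @param green_ph_lo,green_ph_hi Green peak-height acceptance window (a.u.).
#' @param green_pw_min Minimum integrated green width, in samples (strict:
#'   accepted objects have `greenPW > green_pw_min`).
#' @param green_floor Threshold above which green samples count towards the
#'   integrated width; by convention the lower peak-height limit.
#' @param ext_floor Threshold above which extinction samples count towards the
#'   extinction width.
#' @param peak_prominence Minimum drop (a.u.) separating two counted green
#'   local maxima; the peak count is a diagnostic only (two-lobed pharynx),
#'   not part of the accept rule.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(ext_ph = c(2000, 65535), ext_pw = c(60, 1000),
                        green_ph_lo = 700, green_ph_hi = 10000,
                        green_pw_min = 120, green_floor = green_ph_lo,
                        ext_floor = 1000, peak_prominence = 500) {
  if (length(ext_ph) != 2 || length(ext_pw) != 2 ||
      ext_ph[1] > ext_ph[2] || ext_pw[1] > ext_pw[2])
    stop_input("ext_ph and ext_pw must be ordered length-2 ranges")
  if (green_ph_lo >= green_ph_hi)
    stop_input("green_ph_lo must be < green_ph_hi")
  if (green_pw_min < 0) stop_input("green_pw_min must be >= 0")
  structure(list(ext_ph = as.numeric(ext_ph), ext_pw = as.numeric(ext_pw),
                 green_ph_lo = green_ph_lo, green_ph_hi = green_ph_hi,
                 green_pw_min = green_pw_min, green_floor = green_floor,
                 ext_floor = ext_floor, peak_prominence = peak_prominence),
            class = "gate_config")
}

# Count local maxima above `floor` separated by a dip of at least `prom`.
count_peaks <- function(x, floor, prom) {
  idx <- which(x > floor)
  if (length(idx) == 0) return(0L)
  n_peaks <- 0L
  for (run in split(idx, cumsum(c(1L, diff(idx) != 1L)))) {
    z <- x[run]
    if (length(z) < 3) { n_peaks <- n_peaks + 1L; next }
    locmax <- which(diff(sign(diff(z))) < 0) + 1L
    if (length(z) >= 2 && z[1] > z[2]) locmax <- c(1L, locmax)
    if (z[length(z)] > z[length(z) - 1]) locmax <- c(locmax, length(z))
    if (length(locmax) == 0) locmax <- which.max(z)
    # merge maxima not separated by a prominent valley
    kept <- locmax[1]
    for (m in locmax[-1]) {
      valley <- min(z[seq(kept[length(kept)], m)])
      if (min(z[m], z[kept[length(kept)]]) - valley >= prom) kept <- c(kept, m)
      else if (z[m] > z[kept[length(kept)]]) kept[length(kept)] <- m
    }
    n_peaks <- n_peaks + length(kept)
  }
  n_peaks
}

#' Derive Profiler features from a flow profile
#'
#' Peak height is the maximum point measurement along the object. Peak width
#' integrates the widths of *all* areas of the profile exceeding the floor,
#' i.e. it is the total count of super-threshold samples summed over every
#' super-threshold run, not the width of the single largest peak.
#'
#' @param p A [flow_profile()].
#' @param green_floor Green threshold (a.u.) for the width integration.
#' @param ext_floor Extinction threshold (a.u.) for the extinction width.
#' @param peak_prominence Prominence (a.u.) for the diagnostic peak count.
#' @return A list with `green_ph`, `green_pw`, `ext_ph`, `ext_pw`,
#'   `green_peaks`.
#' @export
profile_features <- function(p, green_floor = 700, ext_floor = 1000,
                             peak_prominence = 500) {
  if (!inherits(p, "flow_profile")) stop_input("p must be a flow_profile")
  list(green_ph = max(p$green),
       green_pw = sum(p$green > green_floor),
       ext_ph = max(p$extinction),
       ext_pw = sum(p$extinction > ext_floor),
       green_peaks = count_peaks(p$green, green_floor, peak_prominence))
}

#' Extinction gate test
#'
#' TRUE iff the object's (ExtPH, ExtPW) point lies inside the closed
#' rectangular gating region, the first sorting step that selects worm-sized
#' objects and removes small particles and debris.
#'
#' @param features Feature list from [profile_features()].
#' @param cfg A [gate_config()].
#' @return Logical scalar.
#' @export
gate_extinction <- function(features, cfg = gate_config()) {
  features$ext_ph >= cfg$ext_ph[1] && features$ext_ph <= cfg$ext_ph[2] &&
    features$ext_pw >= cfg$ext_pw[1] && features$ext_pw <= cfg$ext_pw[2]
}

#' Green-profile classification
#'
#' Applies the accept rule for body-GFP homozygotes: green peak height within
#' the configured window and integrated above-floor width strictly greater
#' than the minimum. The rejection reason records the first violated criterion
#' in the fixed order `ph_below`, `ph_above`, `pw_below`.
#'
#' @param features Feature list from [profile_features()] computed with
#'   `green_floor = cfg$green_ph_lo`.
#' @param cfg A [gate_config()].
#' @return A list of class `sort_decision` with `accepted`, `reason`,
#'   `features`.
#' @export
classify_green <- function(features, cfg = gate_config()) {
  reason <- if (features$green_ph < cfg$green_ph_lo) "ph_below"
    else if (features$green_ph > cfg$green_ph_hi) "ph_above"
    else if (features$green_pw <= cfg$green_pw_min) "pw_below"
    else "pass"
  structure(list(accepted = reason == "pass", reason = reason,
                 features = features), class = "sort_decision")
}

#' Sort a population of flow profiles
#'
#' Applies the extinction gate then the green rule to every object. When
#' ground-truth classes are supplied, the efficiency report gives the fraction
#' of objects whose accept/reject decision matches truth (homozygotes should
#' be accepted; heterozygotes and debris rejected), plus false-accept and
#' false-reject rates.
#'
#' @param profiles Non-empty list of [flow_profile()] objects.
#' @param cfg A [gate_config()].
#' @param truth Optional character vector of true classes
#'   (`homozygote`/`heterozygote`/`debris`), same length as `profiles`.
#' @return A list with `decisions` (data.frame: object_id, accepted, reason,
#'   and the five features) and, when truth is given, `report` (efficiency,
#'   false_accept, false_reject, n).
#' @export
sort_population <- function(profiles, cfg = gate_config(), truth = NULL) {
  if (length(profiles) == 0) stop_input("profiles must be non-empty")
  if (!is.null(truth) && length(truth) != length(profiles))
    stop_input("truth length must match profiles")
  n <- length(profiles)
  acc <- logical(n); reason <- character(n)
  gph <- gpw <- eph <- epw <- pk <- numeric(n)
  for (i in seq_len(n)) {
    f <- profile_features(profiles[[i]], green_floor = cfg$green_floor,
                          ext_floor = cfg$ext_floor,
                          peak_prominence = cfg$peak_prominence)
    gph[i] <- f$green_ph; gpw[i] <- f$green_pw
    eph[i] <- f$ext_ph; epw[i] <- f$ext_pw; pk[i] <- f$green_peaks
    if (!gate_extinction(f, cfg)) {
      acc[i] <- FALSE; reason[i] <- "ext_gate_fail"
    } else {
      d <- classify_green(f, cfg)
      acc[i] <- d$accepted; reason[i] <- d$reason
    }
  }
  decisions <- data.frame(object_id = seq_len(n), accepted = acc,
                          reason = reason, green_ph = gph, green_pw = gpw,
                          ext_ph = eph, ext_pw = epw, green_peaks = pk,
                          stringsAsFactors = FALSE)
  out <- list(decisions = decisions)
  if (!is.null(truth)) {
    should_accept <- truth == "homozygote"
    out$report <- list(
      n = length(truth),
      efficiency = mean(decisions$accepted == should_accept),
      false_accept = if (any(!should_accept))
        mean(decisions$accepted[!should_accept]) else 0,
      false_reject = if (any(should_accept))
        mean(!decisions$accepted[should_accept]) else 0)
  }
  out
}
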