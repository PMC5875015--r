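#' Luminescence trace container
#'
#' A per-animal luciferase time series: strictly increasing, uniformly spaced
#' timestamps in minutes and non-negative luminescence in arbitrary units.
#' Feeding larvae ingest luciferin and glow; during each molt feeding stops
#' and the signal drops, which is what the binarization detects.
#'
#' @param time_min Numeric vector of timestamps (minutes), constant spacing.
#' @param lum Numeric vector of luminescence values (a.u., >= 0).
#' @return An object of class `luc_trace`.
#' @export
luc_trace <- function(time_min, lum) {
  if (length(time_min) != length(lum)) stop_input("time and signal lengths differ")
  d <- diff(time_min)
  if (length(d) && (any(d <= 0) || max(abs(d - d[1])) > 1e-8))
    stop_input("timestamps must be strictly increasing with constant spacing")
  if (any(lum < 0)) stop_input("luminescence must be >= 0")
  structure(list(time_min = as.numeric(time_min), lum = as.numeric(lum),
                 sampling_min = if (length(d)) d[1] else NA_real_),
            class = "luc_trace")
}

#' Generate a synthetic luciferase developmental trace with ground truth
#'
#' The signal sits at a feeding plateau during larval stages L1-L4, drops to
#' `molt_frac` of the plateau during each molt M1-M4, continues feeding for
#' `adult_tail_h` hours after the final molt, and is overlaid with a slow
#' exponential decay (luciferin consumption / reporter dilution) and
#' multiplicative noise. A sample exactly on a boundary belongs to the phase
#' that starts there.
#'
#' @param stage_durations_h Durations of L1..L4, hours (all > 0).
#' @param molt_durations_h Durations of M1..M4, hours (all > 0).
#' @param decay Exponential decay rate, per hour.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param sampling_min Sampling interval, minutes (default 5).
#' @param feeding_level Feeding plateau, a.u.
#' @param molt_frac Molt level as a fraction of the plateau.
#' @param adult_tail_h Feeding time recorded after M4, hours.
#' @return List: `trace` ([luc_trace()]), `truth` (data.frame: molt, onset_h,
#'   offset_h).
#' @export
generate_luc_trace <- function(stage_durations_h = c(12, 8, 8, 10),
                               molt_durations_h = c(2, 2, 2, 2.5),
                               decay = 0, noise_cv = 0, seed = 1,
                               sampling_min = 5, feeding_level = 1000,
                               molt_frac = 0.5, adult_tail_h = 3) {
  if (any(c(stage_durations_h, molt_durations_h) <= 0))
    stop_input("all durations must be > 0")
  if (noise_cv < 0) stop_input("noise_cv must be >= 0")
  set.seed(seed)
  bounds <- cumsum(as.vector(rbind(stage_durations_h, molt_durations_h)))
  onsets <- bounds[c(1, 3, 5, 7)]
  offsets <- bounds[c(2, 4, 6, 8)]
  total_h <- bounds[8] + adult_tail_h
  t_h <- seq(0, total_h, by = sampling_min / 60)
  in_molt <- rep(FALSE, length(t_h))
  for (m in 1:4) in_molt <- in_molt | (t_h >= onsets[m] & t_h < offsets[m])
  lum <- feeding_level * ifelse(in_molt, molt_frac, 1) * exp(-decay * t_h)
  lum <- mult_noise(lum, noise_cv)
  list(trace = luc_trace(t_h * 60, lum),
       truth = data.frame(molt = paste0("M", 1:4), onset_h = onsets,
                          offset_h = offsets))
}

#' Binarize a luminescence trace at 75% of a moving average
#'
#' The raw signal is trend-corrected by dividing by a long centered running
#' mean (removing slow decay), then each sample is marked *feeding* iff its
#' corrected value is at least `threshold` (default 0.75) times a centered
#' moving average of the corrected signal, else *molt*. The moving-average
#' window must be longer than the longest molt, otherwise the window can sit
#' entirely inside a molt and the ratio test saturates; the default is 4 h
#' against molts of about 2-2.5 h. A constant trace binarizes to all-feeding;
#' an all-zero trace is degenerate and flagged.
#'
#' @param trace A [luc_trace()].
#' @param ma_window_h Moving-average window, hours.
#' @param trend_window_h Trend-correction window, hours.
#' @param threshold Feeding/molt ratio threshold (default 0.75).
#' @return List of class `luc_binary`: `feeding` (logical), `corrected`,
#'   `ma`, `time_min`, `sampling_min`, `degenerate`.
#' @export
binarize_trace <- function(trace, ma_window_h = 4, trend_window_h = 12,
                           threshold = 0.75) {
  if (!inherits(trace, "luc_trace")) stop_input("trace must be a luc_trace")
  dt_h <- trace$sampling_min / 60
  if (ma_window_h <= dt_h || trend_window_h <= dt_h)
    stop_input("windows must exceed the sampling interval")
  n <- length(trace$lum)
  k_ma <- round(ma_window_h / dt_h)
  k_tr <- round(trend_window_h / dt_h)
  if (n <= max(k_ma, k_tr)) stop_input("trace shorter than the analysis windows")
  if (all(trace$lum == 0))
    return(structure(list(feeding = rep(TRUE, n), corrected = rep(NA_real_, n),
                          ma = rep(NA_real_, n), time_min = trace$time_min,
                          sampling_min = trace$sampling_min, degenerate = TRUE),
                     class = "luc_binary"))
  trend <- running_mean(trace$lum, k_tr)
  corrected <- trace$lum / pmax(trend, .Machine$double.eps)
  ma <- running_mean(corrected, k_ma)
  structure(list(feeding = corrected >= threshold * ma, corrected = corrected,
                 ma = ma, time_min = trace$time_min,
                 sampling_min = trace$sampling_min, degenerate = FALSE),
            class = "luc_binary")
}

#' Detect molts and extract a stage/molt schedule
#'
#' Scans the binarized trace for contiguous molt (non-feeding) runs, ignores
#' runs shorter than the debounce duration, and takes the first four
#' surviving runs as M1..M4. Larval-stage durations are the gaps: L1 from the
#' start of the trace to M1 onset, L2..L4 between consecutive molts. A
#' schedule with fewer than four molts is returned partial, with
#' `complete = FALSE`.
#'
#' @param bin A `luc_binary` from [binarize_trace()].
#' @param debounce_min Minimum molt duration, minutes (default 30).
#' @return An object of class `molt_schedule`: `molts` (data.frame: molt,
#'   onset_h, offset_h, duration_h), `stages` (data.frame: stage,
#'   duration_h), `complete`, `degenerate`.
#' @export
detect_molts <- function(bin, debounce_min = 30) {
  if (!inherits(bin, "luc_binary")) stop_input("bin must be a luc_binary")
  dt_h <- bin$sampling_min / 60
  t0_h <- bin$time_min[1] / 60
  empty <- data.frame(molt = character(), onset_h = numeric(),
                      offset_h = numeric(), duration_h = numeric())
  if (bin$degenerate)
    return(structure(list(molts = empty,
                          stages = data.frame(stage = character(),
                                              duration_h = numeric()),
                          complete = FALSE, degenerate = TRUE),
                     class = "molt_schedule"))
  r <- rle(bin$feeding)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_molt <- !r$values & r$lengths * bin$sampling_min >= debounce_min
  mi <- which(is_molt)
  mi <- mi[seq_len(min(4L, length(mi)))]
  molts <- if (length(mi)) data.frame(
    molt = paste0("M", seq_along(mi)),
    onset_h = bin$time_min[starts[mi]] / 60,
    offset_h = (bin$time_min[ends[mi]] + bin$sampling_min) / 60,
    duration_h = r$lengths[mi] * dt_h) else empty
  stages <- if (length(mi)) data.frame(
    stage = paste0("L", seq_along(mi)),
    duration_h = molts$onset_h - c(t0_h, molts$offset_h[-length(mi)])) else
    data.frame(stage = character(), duration_h = numeric())
  structure(list(molts = molts, stages = stages,
                 complete = length(mi) == 4L, degenerate = FALSE),
            class = "molt_schedule")
}

#' @export
print.molt_schedule <- function(x, ...) {
  cat(sprintf("<molt_schedule> %d molt(s)%s\n", nrow(x$molts),
              if (x$complete) "" else " [partial]"))
  if (nrow(x$molts)) print(x$molts)
  invisible(x)
}
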