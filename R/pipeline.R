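#' Run the screening workflow end to end on synthetic data
#'
#' Generates a phantom screen from a plate layout and an effect map, produces
#' per-worm records, runs the statistics pipeline and calls hits, returning a
#' manifest that makes the run reproducible. Two modes:
#'
#' * `"tables"` (default): per-worm records come straight from the tabular
#'   phantom generator — fast, suitable for many plates;
#' * `"images"`: every non-empty well is rendered as a whole-well image set,
#'   segmented and measured, and the measured records (with the plate map
#'   joined) feed the statistics — the full imaging workflow at small scale.
#'
#' Re-running with the same spec and seed reproduces the hit table exactly.
#'
#' @param spec A list: `layout` (plate map, see [validate_plate_map()]),
#'   `effects` (named clone -> fold-change map), `worms_per_well`,
#'   `noise_cv`, `contamination`, `readout` (`"reporter"`/`"size"`), `mode`
#'   (`"tables"`/`"images"`), and for image mode `control_gfp` (mean control
#'   body GFP, default 300).
#' @param seed Integer root seed; all stage seeds derive from it.
#' @param out_dir Optional directory; when given, records, per-well stats,
#'   hits and the JSON manifest are written there.
#' @param cfg A [screen_config()].
#' @param seg_cfg A [seg_config()] (image mode only).
#' @return List: `hits`, `stats`, `qc`, `audit`, `records`, `truth`,
#'   `manifest`.
#' @export
run_end_to_end <- function(spec, seed = 1, out_dir = NULL,
                           cfg = screen_config(), seg_cfg = seg_config()) {
  if (is.null(spec$layout)) stop_input("spec$layout (plate map) is required")
  validate_plate_map(spec$layout)
  mode <- spec$mode %||% "tables"
  readout <- spec$readout %||% "reporter"
  worms_per_well <- spec$worms_per_well %||% 30
  noise_cv <- spec$noise_cv %||% 0.3
  contamination <- spec$contamination %||% 0

  stage <- "phantoms"
  result <- tryCatch({
    if (mode == "tables") {
      gen <- generate_screen_tables(spec$layout, effects = spec$effects,
                                    worms_per_well = worms_per_well,
                                    noise_cv = noise_cv,
                                    contamination = contamination,
                                    small_larva_rate = spec$small_larva_rate %||% 0,
                                    seed = seed)
      records <- gen$records
      truth <- gen$truth
    } else {
      gen <- simulate_image_plate(spec, seed, seg_cfg,
                                  worms_per_well, noise_cv, contamination)
      records <- gen$records
      truth <- gen$truth
    }
    stage <- "screenstats"
    scr <- run_screen(records, cfg, readout, seed = seed)
    c(scr, list(records = records, truth = truth))
  }, error = function(e) {
    stop_input("end-to-end run failed at stage '", stage, "': ",
               conditionMessage(e))
  })

  manifest <- list(run_id = sprintf("run_%d", seed), seed = seed,
                   mode = mode, readout = readout,
                   config = list(screen = unclass(cfg),
                                 segmentation = if (mode == "images")
                                   unclass(seg_cfg)),
                   n_records = nrow(result$records),
                   n_hits = sum(result$hits$category != "none" &
                                  result$hits$role == "sample"),
                   tool_version = as.character(utils::packageVersion("wormscreen")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(records = file.path(out_dir, "records.csv"),
               stats = file.path(out_dir, "well_stats.csv"),
               hits = file.path(out_dir, "hits.csv"))
    utils::write.csv(result$records, paths["records"], row.names = FALSE)
    utils::write.csv(result$stats, paths["stats"], row.names = FALSE)
    utils::write.csv(result$hits, paths["hits"], row.names = FALSE)
    manifest$outputs <- lapply(stats::setNames(nm = names(paths)), function(nm)
      list(path = unname(paths[nm]),
           md5 = unname(tools::md5sum(paths[nm]))))
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  result$manifest <- manifest
  result
}

# Image-mode plate simulation: render, segment and measure every non-empty
# well, joining the plate map onto the measured records.
simulate_image_plate <- function(spec, seed, seg_cfg, worms_per_well,
                                 noise_cv, contamination) {
  layout <- spec$layout
  wells <- layout[layout$role != "empty", , drop = FALSE]
  control_gfp <- spec$control_gfp %||% 300
  effects <- spec$effects %||% numeric(0)
  well_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                           nrow(wells)))
  rows <- list(); truth_rows <- list()
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    fc <- if (w$role == "control_pos") spec$pos_control_fc %||% 0.15
      else if (w$role == "control_neg") 1
      else if (!is.na(w$clone_id) && w$clone_id %in% names(effects))
        as.numeric(effects[[w$clone_id]]) else 1
    n_het <- with_seed(well_seeds[i] %% 1000L + 1L,
                       stats::rbinom(1, worms_per_well, contamination))
    n_hom <- worms_per_well - n_het
    ph <- generate_well_image(n_hom, n_het, seed = well_seeds[i],
                              body_gfp_mean = control_gfp * fc,
                              body_gfp_cv = noise_cv, well_id = w$well)
    seg <- segment_well_set(ph$images, seg_cfg)
    rec <- measure_worms(seg, ph$images)
    if (nrow(rec)) {
      rec$plate_id <- w$plate_id
      rec$clone_id <- w$clone_id
      rec$role <- w$role
      names(rec)[names(rec) == "well_id"] <- "well"
      rows[[length(rows) + 1]] <- rec
    }
    truth_rows[[i]] <- data.frame(plate_id = w$plate_id, well = w$well,
                                  clone_id = w$clone_id, role = w$role,
                                  true_fc = fc, n_hom = n_hom, n_het = n_het,
                                  stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rows), truth = do.call(rbind, truth_rows))
}
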