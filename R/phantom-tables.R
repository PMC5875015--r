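#' Generate a synthetic per-worm screen table with ground truth
#'
#' Tabular stand-in for a fully imaged screen: per-worm background-subtracted
#' GFP values drawn lognormally around the plate control mean times each
#' clone's fold change, plus the two nuisances the worm filters exist for —
#' balancer-heterozygote contaminants (progeny with `green_head_id >= 1` and
#' larval lengths) and small larvae among the homozygotes.
#'
#' @param layout Plate map (see [validate_plate_map()]); every plate needs
#'   >= 4 negative-control wells.
#' @param effects Named numeric vector/list mapping `clone_id` to true fold
#'   change; clones absent from it default to 1.0.
#' @param worms_per_well Worms drawn per non-empty well.
#' @param noise_cv Between-worm lognormal CV of the GFP value.
#' @param contamination Probability a worm is a green-headed contaminant.
#' @param small_larva_rate Probability a non-contaminant worm is a small
#'   larva (length below the 550 µm filter).
#' @param seed Integer seed.
#' @param control_mean True control GFP level, a.u. (default 300, the centre
#'   of the 200-500 a.u. QC window).
#' @param pos_control_fc Fold change of positive-control wells (strong
#'   suppressor).
#' @param length_mean,length_sd Adult worm length distribution, µm.
#' @param larva_length_range Length range of small larvae / progeny, µm.
#' @return List: `records` (per-worm data.frame: plate_id, well, clone_id,
#'   role, worm, int_worm_minus_bkgd_green, length_um, green_head_id),
#'   `truth` (per-well data.frame with `true_fc`).
#' @export
generate_screen_tables <- function(layout, effects = NULL, worms_per_well = 30,
                                   noise_cv = 0.3, contamination = 0,
                                   small_larva_rate = 0, seed = 1,
                                   control_mean = 300, pos_control_fc = 0.15,
                                   length_mean = 950, length_sd = 60,
                                   larva_length_range = c(250, 500)) {
  validate_plate_map(layout)
  if (contamination < 0 || contamination > 1)
    stop_input("contamination must be in [0, 1]")
  set.seed(seed)
  effects <- effects %||% numeric(0)
  wells <- layout[layout$role != "empty", , drop = FALSE]
  rows <- vector("list", nrow(wells))
  truth <- wells[c("plate_id", "well", "clone_id", "role")]
  truth$true_fc <- NA_real_
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    fc <- if (w$role == "control_pos") pos_control_fc
      else if (w$role == "control_neg") 1
      else if (!is.na(w$clone_id) && w$clone_id %in% names(effects))
        as.numeric(effects[[w$clone_id]]) else 1
    truth$true_fc[i] <- fc
    n <- worms_per_well
    contam <- stats::runif(n) < contamination
    small <- !contam & stats::runif(n) < small_larva_rate
    len <- stats::rnorm(n, length_mean, length_sd)
    len[contam | small] <- stats::runif(sum(contam | small),
                                        larva_length_range[1],
                                        larva_length_range[2])
    val <- rlnorm_mean_cv(n, control_mean * fc, noise_cv)
    # contaminant heterozygotes carry the balancer, not the induced reporter
    val[contam] <- rlnorm_mean_cv(sum(contam), control_mean * 0.3, noise_cv)
    rows[[i]] <- data.frame(plate_id = w$plate_id, well = w$well,
                            clone_id = w$clone_id, role = w$role,
                            worm = seq_len(n),
                            int_worm_minus_bkgd_green = val,
                            length_um = len,
                            green_head_id = as.integer(contam),
                            stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rows), truth = truth)
}
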