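#' Screen analysis configuration
#'
#' Thresholds of the screen-statistics pipeline. Defaults are the published
#' rules of the workflow: worms with any green head discarded; reporter
#' readout also drops worms shorter than 550 µm and trims each well's values
#' strictly outside its 5th/95th percentiles; wells keep >= 5 worms;
#' negative-control wells pass QC with mean GFP in \[200, 500\] a.u. and
#' CV < 0.5, and a plate needs >= 2 passing control wells; candidates require
#' adjusted p < 0.001 with FC < 0.66 (down) or FC > 1.5 (up) for the reporter
#' readout, and FC < 0.85 (no p condition) for the size readout. All
#' inequalities on FC and p are strict.
#'
#' @param min_length_um Minimum worm length for the reporter readout (µm).
#' @param trim_percentiles Per-well trim percentiles (lower, upper).
#' @param min_worms_per_well Minimum surviving worms per analysed well.
#' @param qc_mean_window Accepted control-well mean GFP window (a.u.,
#'   inclusive).
#' @param qc_cv_max Maximum control-well coefficient of variation (strict).
#' @param min_control_wells Minimum accepted negative-control wells per plate.
#' @param p_threshold Adjusted p-value threshold (strict).
#' @param fc_down,fc_up Reporter fold-change thresholds (strict).
#' @param fc_size Size-readout fold-change threshold (strict).
#' @param size_requires_p If TRUE, size hits additionally require
#'   `p < p_threshold` (off by default, matching the published rule).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(min_length_um = 550, trim_percentiles = c(5, 95),
                          min_worms_per_well = 5, qc_mean_window = c(200, 500),
                          qc_cv_max = 0.5, min_control_wells = 2,
                          p_threshold = 0.001, fc_down = 0.66, fc_up = 1.5,
                          fc_size = 0.85, size_requires_p = FALSE) {
  if (!(fc_down < 1 && 1 < fc_up)) stop_input("need fc_down < 1 < fc_up")
  if (any(c(min_length_um, min_worms_per_well, qc_cv_max, p_threshold,
            fc_size) <= 0))
    stop_input("thresholds must be positive")
  structure(as.list(environment()), class = "screen_config")
}

#' Validate a plate map
#'
#' A plate map has one row per well: `plate_id`, `well`, `clone_id`, `gene`
#' (optional) and `role` in `sample` / `control_neg` / `control_pos` /
#' `empty`. Every plate must designate at least four negative-control wells.
#'
#' @param map A data.frame.
#' @return The map, invisibly, after validation.
#' @export
validate_plate_map <- function(map) {
  need <- c("plate_id", "well", "clone_id", "role")
  if (!all(need %in% names(map)))
    stop_input("plate map needs columns: ", paste(need, collapse = ", "))
  bad <- vapply(split(map, map$plate_id),
                function(p) sum(p$role == "control_neg") < 4, logical(1))
  if (any(bad))
    stop_input("plates without >= 4 negative-control wells: ",
               paste(names(bad)[bad], collapse = ", "))
  invisible(map)
}

#' Build a default single-or-multi-plate layout
#'
#' Samples fill columns 1..11 column-major; the last column is reserved for
#' controls: four negative controls (rows A-D), one positive control (row E),
#' the rest empty.
#'
#' @param n_plates Number of plates.
#' @param clones Optional character vector of clone ids to lay out (defaults
#'   to `clone_0001`...).
#' @param n_sample_wells Sample wells per plate (<= 88).
#' @return A plate-map data.frame.
#' @export
default_plate_map <- function(n_plates = 1, clones = NULL,
                              n_sample_wells = 88) {
  stopifnot(n_sample_wells <= 88)
  maps <- lapply(seq_len(n_plates), function(p) {
    wells <- as.vector(outer(LETTERS[1:8], sprintf("%02d", 1:11),
                             function(r, c) paste0(r, c)))[seq_len(n_sample_wells)]
    smp <- data.frame(plate_id = sprintf("P%02d", p), well = wells,
                      clone_id = NA_character_, gene = NA_character_,
                      role = "sample", stringsAsFactors = FALSE)
    ctl <- data.frame(plate_id = sprintf("P%02d", p),
                      well = paste0(LETTERS[1:8], "12"),
                      clone_id = c(rep("empty_vector", 4), "atfs-1",
                                   rep(NA_character_, 3)),
                      gene = NA_character_,
                      role = c(rep("control_neg", 4), "control_pos",
                               rep("empty", 3)), stringsAsFactors = FALSE)
    rbind(smp, ctl)
  })
  map <- do.call(rbind, maps)
  idx <- which(map$role == "sample")
  map$clone_id[idx] <- if (is.null(clones))
    sprintf("clone_%04d", seq_along(idx)) else
    rep_len(c(clones, rep(NA_character_, length(idx))), length(idx))
  keep <- !(map$role == "sample" & is.na(map$clone_id))
  map <- map[keep, , drop = FALSE]
  rownames(map) <- NULL
  validate_plate_map(map)
  map
}

#' Worm-level filters
#'
#' Reporter readout: (1) discard worms with a green pharynx
#' (`green_head_id > 0`); (2) discard worms shorter than `min_length_um`;
#' (3) per well, discard values strictly below the 5th or strictly above the
#' 95th percentile of that well's analysis value (linearly interpolated
#' quantiles). Size readout: only the green-pharynx filter, keeping all worms
#' irrespective of size.
#'
#' @param records Per-worm data.frame with `plate_id`, `well`,
#'   `green_head_id`, `length_um` and the analysis value column.
#' @param cfg A [screen_config()].
#' @param readout `"reporter"` or `"size"`.
#' @param value_col Analysis value column; defaults to
#'   `int_worm_minus_bkgd_green` (reporter) or `length_um` (size).
#' @return List: `records` (survivors), `audit` (counts removed per rule, in
#'   application order), `value_col`.
#' @export
filter_worms <- function(records, cfg = screen_config(),
                         readout = c("reporter", "size"), value_col = NULL) {
  readout <- match.arg(readout)
  value_col <- value_col %||%
    if (readout == "reporter") "int_worm_minus_bkgd_green" else "length_um"
  audit <- list(input = nrow(records))
  keep <- records$green_head_id == 0
  audit$green_head <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (readout == "reporter") {
    keep <- records$length_um >= cfg$min_length_um
    audit$short <- sum(!keep)
    records <- records[keep, , drop = FALSE]
    wellkey <- interaction(records$plate_id, records$well, drop = TRUE)
    keep <- rep(TRUE, nrow(records))
    for (w in levels(wellkey)) {
      i <- which(wellkey == w)
      q <- stats::quantile(records[[value_col]][i],
                           cfg$trim_percentiles / 100, type = 7, names = FALSE)
      keep[i] <- records[[value_col]][i] >= q[1] & records[[value_col]][i] <= q[2]
    }
    audit$percentile_trim <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  audit$output <- nrow(records)
  list(records = records, audit = audit, value_col = value_col)
}

#' Well-level filter
#'
#' Removes wells with fewer than `min_worms_per_well` surviving worms
#' (strictly fewer: a five-worm well is kept).
#'
#' @param records Filtered per-worm records.
#' @param cfg A [screen_config()].
#' @return List: `records`, `dropped_wells` (data.frame plate_id/well/n).
#' @export
filter_wells <- function(records, cfg = screen_config()) {
  if (nrow(records) == 0)
    return(list(records = records,
                dropped_wells = data.frame(plate_id = character(),
                                           well = character(), n = integer())))
  key <- interaction(records$plate_id, records$well, drop = TRUE)
  counts <- table(key)
  bad <- names(counts)[counts < cfg$min_worms_per_well]
  dropped <- do.call(rbind, lapply(bad, function(b) {
    i <- which(key == b)[1]
    data.frame(plate_id = records$plate_id[i], well = records$well[i],
               n = as.integer(counts[b]), stringsAsFactors = FALSE)
  }))
  list(records = records[!(key %in% bad), , drop = FALSE],
       dropped_wells = dropped %||%
         data.frame(plate_id = character(), well = character(), n = integer()))
}

#' Plate quality control on negative-control wells
#'
#' Each negative-control well is accepted iff its mean GFP lies inside the QC
#' window (inclusive) and its coefficient of variation is strictly below the
#' maximum. A plate passes iff at least `min_control_wells` control wells are
#' accepted.
#'
#' @param records Filtered per-worm records (one or more plates).
#' @param cfg A [screen_config()].
#' @param value_col Analysis value column.
#' @return List of per-plate entries: `controls` (well, n, mean, cv,
#'   accepted, reason) and `pass`.
#' @export
qc_plate <- function(records, cfg = screen_config(),
                     value_col = "int_worm_minus_bkgd_green") {
  out <- list()
  for (p in unique(records$plate_id)) {
    ctl <- records[records$plate_id == p & records$role == "control_neg", ,
                   drop = FALSE]
    wells <- unique(ctl$well)
    tab <- do.call(rbind, lapply(wells, function(w) {
      v <- ctl[[value_col]][ctl$well == w]
      m <- mean(v)
      cv <- if (length(v) >= 2 && m != 0) stats::sd(v) / m else NA_real_
      reason <- if (m < cfg$qc_mean_window[1]) "mean_below"
        else if (m > cfg$qc_mean_window[2]) "mean_above"
        else if (is.na(cv) || cv >= cfg$qc_cv_max) "cv"
        else "pass"
      data.frame(well = w, n = length(v), mean = m, cv = cv,
                 accepted = reason == "pass", reason = reason,
                 stringsAsFactors = FALSE)
    })) %||% data.frame(well = character(), n = integer(), mean = numeric(),
                        cv = numeric(), accepted = logical(),
                        reason = character())
    out[[p]] <- list(controls = tab, pass = sum(tab$accepted) >= cfg$min_control_wells)
  }
  out
}

#' Normalize a plate by its accepted negative controls
#'
#' Divides every worm's value by the grand mean over the worms in the
#' accepted negative-control wells of its plate, so the pooled control-well
#' normalized mean is exactly 1. Plates that failed QC, or whose control mean
#' is not strictly positive, are flagged and their `value_norm` left `NA`.
#'
#' @param records Filtered per-worm records.
#' @param qc Result of [qc_plate()].
#' @param value_col Analysis value column.
#' @return List: `records` (with `value_norm` column), `plate_flags` (named
#'   logical: TRUE = usable plate), `divisors` (named numeric).
#' @export
normalize_plate <- function(records, qc,
                            value_col = "int_worm_minus_bkgd_green") {
  records$value_norm <- NA_real_
  flags <- divisors <- stats::setNames(rep(NA, 0), character(0))
  for (p in unique(records$plate_id)) {
    i <- records$plate_id == p
    ok <- qc[[p]]$pass %||% FALSE
    div <- NA_real_
    if (ok) {
      acc_wells <- qc[[p]]$controls$well[qc[[p]]$controls$accepted]
      ctl <- i & records$role == "control_neg" & records$well %in% acc_wells
      div <- mean(records[[value_col]][ctl])
      if (!is.finite(div) || div <= 0) ok <- FALSE
    }
    if (ok) records$value_norm[i] <- records[[value_col]][i] / div
    flags[p] <- ok
    divisors[p] <- div
  }
  list(records = records, plate_flags = flags, divisors = divisors)
}

#' Per-well ANOVA + Dunnett testing
#'
#' For each usable plate, fits a one-way ANOVA across wells with individual
#' worms as replicates, pooling the accepted negative-control wells into one
#' reference group, then performs Dunnett many-to-one comparisons of every
#' other well against that pooled control (two-sided, single-step adjusted
#' p-values from the equicorrelation-aware multivariate-t distribution). The
#' fold change of a well is the mean of its normalized values. Wells with
#' fewer than two worms are excluded from testing and recorded in the audit.
#'
#' @param norm Result of [normalize_plate()].
#' @param qc Result of [qc_plate()].
#' @param cfg A [screen_config()].
#' @param seed Integer seed for the (quasi-random) multivariate-t integration,
#'   making adjusted p-values reproducible.
#' @return List: `stats` (data.frame: plate_id, well, clone_id, role, n,
#'   fc, p_adj, p_anova), `audit` (excluded single-worm wells).
#' @export
test_wells <- function(norm, qc, cfg = screen_config(), seed = 1) {
  records <- norm$records
  stats_rows <- list(); audit <- list()
  for (p in names(norm$plate_flags)[norm$plate_flags]) {
    dat <- records[records$plate_id == p & !is.na(records$value_norm), ,
                   drop = FALSE]
    acc_wells <- qc[[p]]$controls$well[qc[[p]]$controls$accepted]
    grp <- ifelse(dat$role == "control_neg" & dat$well %in% acc_wells,
                  "control", dat$well)
    counts <- table(grp)
    small <- setdiff(names(counts)[counts < 2], "control")
    if (length(small)) {
      audit[[p]] <- small
      keep <- !(grp %in% small)
      dat <- dat[keep, , drop = FALSE]; grp <- grp[keep]
    }
    if (length(unique(grp)) < 2 || !("control" %in% grp)) next
    dat$g <- stats::relevel(factor(grp), ref = "control")
    fit <- stats::aov(value_norm ~ g, data = dat)
    p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
    dn <- with_seed(seed, {
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
      s <- summary(gl)
      list(p = as.numeric(s$test$pvalues), names = rownames(s$linfct))
    })
    padj <- dn$p
    comp_wells <- sub(" - control$", "", dn$names)
    fc <- tapply(dat$value_norm, dat$g, mean)
    meta <- dat[!duplicated(dat$well), c("well", "clone_id", "role")]
    for (j in seq_along(comp_wells)) {
      w <- comp_wells[j]
      m <- meta[meta$well == w, , drop = FALSE]
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        plate_id = p, well = w,
        clone_id = if (nrow(m)) m$clone_id[1] else NA_character_,
        role = if (nrow(m)) m$role[1] else NA_character_,
        n = as.integer(sum(dat$g == w)),
        fc = as.numeric(fc[[w]]), p_adj = as.numeric(padj[j]),
        p_anova = p_anova, stringsAsFactors = FALSE)
    }
  }
  list(stats = do.call(rbind, stats_rows) %||%
         data.frame(plate_id = character(), well = character(),
                    clone_id = character(), role = character(), n = integer(),
                    fc = numeric(), p_adj = numeric(), p_anova = numeric()),
       audit = audit)
}

#' Call hits from per-well statistics
#'
#' Reporter readout: `down` iff `p_adj < p_threshold` and `fc < fc_down`;
#' `up` iff `p_adj < p_threshold` and `fc > fc_up`. Size readout: `down` iff
#' `fc < fc_size` (optionally also requiring the p condition). All
#' inequalities strict; boundary values are `none`.
#'
#' @param stats Per-well statistics from [test_wells()].
#' @param cfg A [screen_config()].
#' @param readout `"reporter"` or `"size"`.
#' @return `stats` with a `category` column (`down` / `up` / `none`).
#' @export
call_hits <- function(stats, cfg = screen_config(),
                      readout = c("reporter", "size")) {
  readout <- match.arg(readout)
  cat_ <- rep("none", nrow(stats))
  if (readout == "reporter") {
    sig <- stats$p_adj < cfg$p_threshold
    cat_[sig & stats$fc < cfg$fc_down] <- "down"
    cat_[sig & stats$fc > cfg$fc_up] <- "up"
  } else {
    down <- stats$fc < cfg$fc_size
    if (cfg$size_requires_p) down <- down & stats$p_adj < cfg$p_threshold
    cat_[down] <- "down"
  }
  stats$category <- cat_
  stats
}

#' Run the full screen-statistics pipeline
#'
#' Applies, in order: worm filters, well filter, plate QC, negative-control
#' normalization, ANOVA + Dunnett testing and hit calling, collecting an
#' audit trail at every stage.
#'
#' @param records Per-worm records joined to a plate map (columns `plate_id`,
#'   `well`, `clone_id`, `role`, `green_head_id`, `length_um` and the value
#'   column).
#' @param cfg A [screen_config()].
#' @param readout `"reporter"` or `"size"`.
#' @param seed Seed forwarded to [test_wells()].
#' @return List: `hits`, `stats`, `qc`, `audit`.
#' @export
run_screen <- function(records, cfg = screen_config(),
                       readout = c("reporter", "size"), seed = 1) {
  readout <- match.arg(readout)
  fw <- filter_worms(records, cfg, readout)
  fl <- filter_wells(fw$records, cfg)
  qc <- qc_plate(fl$records, cfg, value_col = fw$value_col)
  norm <- normalize_plate(fl$records, qc, value_col = fw$value_col)
  st <- test_wells(norm, qc, cfg, seed = seed)
  hits <- call_hits(st$stats, cfg, readout)
  list(hits = hits, stats = st$stats, qc = qc,
       audit = list(worm_filters = fw$audit,
                    dropped_wells = fl$dropped_wells,
                    plate_flags = norm$plate_flags,
                    excluded_groups = st$audit))
}

#' Lay out an RNAi library over 96-well plates
#'
#' Clones fill plates column-major over the usable wells, leaving the last
#' `reserved_columns` column(s) of each plate empty for controls (8 wells per
#' reserved column), so a 96-well plate with one reserved column holds 88
#' clones and the plate count is `ceiling(n_clones / 88)`.
#'
#' @param n_clones Number of clones (>= 0).
#' @param wells_per_plate Wells per plate (default 96, i.e. 8 rows x 12
#'   columns).
#' @param reserved_columns Columns reserved for controls.
#' @return List: `n_plates`, `usable_wells_per_plate`, `manifest` (data.frame
#'   clone index -> plate, well).
#' @export
layout_library <- function(n_clones, wells_per_plate = 96,
                           reserved_columns = 1) {
  if (n_clones < 0) stop_input("n_clones must be >= 0")
  n_rows <- 8L
  n_cols <- as.integer(wells_per_plate / n_rows)
  usable_cols <- n_cols - reserved_columns
  usable <- n_rows * usable_cols
  n_plates <- as.integer(ceiling(n_clones / usable))
  if (n_clones == 0)
    return(list(n_plates = 0L, usable_wells_per_plate = usable,
                manifest = data.frame(clone = integer(), plate = integer(),
                                      well = character())))
  i <- seq_len(n_clones) - 1L
  pos <- i %% usable
  manifest <- data.frame(
    clone = i + 1L, plate = i %/% usable + 1L,
    well = sprintf("%s%02d", LETTERS[pos %% n_rows + 1L], pos %/% n_rows + 1L),
    stringsAsFactors = FALSE)
  list(n_plates = n_plates, usable_wells_per_plate = usable,
       manifest = manifest)
}

#' Library sequencing reliability report
#'
#' @param n_sequenced Clones sequenced.
#' @param n_correct Clones identified correctly (0 <= n_correct <=
#'   n_sequenced).
#' @return List: `fraction`, `percent` (exact), `percent_rounded` (nearest
#'   integer).
#' @export
library_qc_report <- function(n_sequenced, n_correct) {
  if (n_sequenced <= 0 || n_correct < 0 || n_correct > n_sequenced)
    stop_input("need 0 <= n_correct <= n_sequenced and n_sequenced > 0")
  frac <- n_correct / n_sequenced
  list(fraction = frac, percent = 100 * frac,
       percent_rounded = as.integer(round(100 * frac)))
}
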