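# Filters, QC, normalization, Dunnett testing, hit calling, library layout.

test_that("worm filters reproduce hand-computed survivor counts per readout", {
  rec <- rbind(worm_rows(well = "A01", n = 2, head = 1),
               worm_rows(well = "A01", n = 1, length_um = 400),
               worm_rows(well = "A01", n = 7,
                         value = c(250, 260, 270, 280, 290, 300, 310)))
  rep_f <- filter_worms(rec, screen_config(), "reporter")
  expect_equal(rep_f$audit$green_head, 2)
  expect_equal(rep_f$audit$short, 1)
  expect_equal(rep_f$audit$input - rep_f$audit$green_head - rep_f$audit$short,
               7)  # survivors before the percentile trim
  # 7 distinct values: the strict 5th/95th trim removes the two extremes
  expect_equal(rep_f$audit$percentile_trim, 2)
  expect_equal(nrow(rep_f$records), 5)

  size_f <- filter_worms(rec, screen_config(), "size")
  expect_equal(nrow(size_f$records), 8)
  expect_equal(size_f$value_col, "length_um")

  ties <- worm_rows(well = "B01", n = 20, value = 300)
  tie_f <- filter_worms(ties, screen_config(), "reporter")
  expect_equal(tie_f$audit$percentile_trim, 0)
})

test_that("wells keep five worms but drop four, and empty input is not an error", {
  rec <- rbind(worm_rows(well = "A01", n = 4),
               worm_rows(well = "A02", n = 5))
  fl <- filter_wells(rec, screen_config())
  expect_setequal(unique(fl$records$well), "A02")
  expect_equal(fl$dropped_wells$well, "A01")
  expect_equal(fl$dropped_wells$n, 4)
  empty <- filter_wells(rec[0, ], screen_config())
  expect_equal(nrow(empty$records), 0)
})

test_that("control-well QC applies the intensity window and CV rule", {
  z <- c(-1.5, -0.5, 0.5, 1.5) / stats::sd(c(-1.5, -0.5, 0.5, 1.5))
  mkctl <- function(well, mean, cv)
    worm_rows(well = well, n = 4, value = mean * (1 + cv * z),
              role = "control_neg", clone = "empty_vector")
  rec <- rbind(mkctl("A12", 350, 0.3),   # accepted
               mkctl("B12", 0, 0.1),     # mean below window
               mkctl("C12", 600, 0.1),   # mean above window
               mkctl("D12", 350, 0.6))   # CV too high
  qc <- qc_plate(rec, screen_config())
  ctl <- qc$P01$controls
  expect_equal(ctl$accepted[match(c("A12", "B12", "C12", "D12"), ctl$well)],
               c(TRUE, FALSE, FALSE, FALSE))
  expect_false(qc$P01$pass)   # only one accepted control -> plate discarded

  rec2 <- rbind(mkctl("A12", 350, 0.3), mkctl("B12", 250, 0.2),
                mkctl("C12", 490, 0.45), mkctl("D12", 350, 0.6))
  expect_true(qc_plate(rec2, screen_config())$P01$pass)
})

test_that("normalization divides by the accepted-control mean, landing controls at 1", {
  rec <- rbind(worm_rows(well = "A12", n = 6, value = 300,
                         role = "control_neg"),
               worm_rows(well = "B12", n = 6, value = 300,
                         role = "control_neg"),
               worm_rows(well = "A01", n = 6, value = 150))
  qc <- qc_plate(rec, screen_config(min_control_wells = 2))
  norm <- normalize_plate(rec, qc)
  r <- norm$records
  expect_equal(mean(r$value_norm[r$role == "control_neg"]), 1)
  expect_equal(unique(r$value_norm[r$well == "A01"]), 0.5)
  expect_equal(unname(norm$divisors["P01"]), 300)
})

test_that("a two-group plate reduces Dunnett to the ordinary pooled t-test", {
  set.seed(77)
  rec <- rbind(worm_rows(well = "A12", n = 10,
                         value = 300 + rnorm(10, 0, 30), role = "control_neg"),
               worm_rows(well = "B12", n = 10,
                         value = 300 + rnorm(10, 0, 30), role = "control_neg"),
               worm_rows(well = "A01", n = 10,
                         value = 270 + rnorm(10, 0, 30)))
  qc <- qc_plate(rec, screen_config())
  norm <- normalize_plate(rec, qc)
  st <- test_wells(norm, qc, screen_config(), seed = 1)
  r <- norm$records
  tt <- stats::t.test(r$value_norm[r$well == "A01"],
                      r$value_norm[r$role == "control_neg"],
                      var.equal = TRUE)
  expect_lt(abs(st$stats$p_adj[st$stats$well == "A01"] - tt$p.value), 1e-6)
})

test_that("Dunnett adjusted p-values exceed unadjusted model-based p-values", {
  map <- default_plate_map(1, n_sample_wells = 6)
  gen <- generate_screen_tables(map, worms_per_well = 10, noise_cv = 0.3,
                                seed = 15)
  fw <- filter_worms(gen$records, screen_config(), "reporter")
  fl <- filter_wells(fw$records, screen_config())
  qc <- qc_plate(fl$records, screen_config())
  norm <- normalize_plate(fl$records, qc)
  st <- test_wells(norm, qc, screen_config(), seed = 1)$stats
  # unadjusted p from the same pooled-variance model, first principles
  r <- norm$records
  grp <- ifelse(r$role == "control_neg", "control", r$well)
  groups <- split(r$value_norm, grp)
  df <- sum(lengths(groups)) - length(groups)
  sp <- sqrt(sum(vapply(groups, function(g) sum((g - mean(g))^2),
                        numeric(1))) / df)
  for (w in st$well) {
    t_w <- (mean(groups[[w]]) - mean(groups$control)) /
      (sp * sqrt(1 / length(groups[[w]]) + 1 / length(groups$control)))
    p_raw <- 2 * stats::pt(-abs(t_w), df)
    expect_gte(st$p_adj[st$well == w] + 1e-9, p_raw)
  }
})

test_that("single-worm wells are excluded from testing with an audit entry", {
  rec <- rbind(worm_rows(well = "A12", n = 6, value = 300 + (-2:3) * 8,
                         role = "control_neg"),
               worm_rows(well = "B12", n = 6, value = 300 + (-3:2) * 7,
                         role = "control_neg"),
               worm_rows(well = "A01", n = 6, value = 280 + (-2:3) * 9),
               worm_rows(well = "A02", n = 1, value = 280, clone = "cloneY"))
  qc <- qc_plate(rec, screen_config())
  norm <- normalize_plate(rec, qc)
  st <- test_wells(norm, qc, screen_config(min_worms_per_well = 1), seed = 1)
  expect_false("A02" %in% st$stats$well)
  expect_equal(st$audit$P01, "A02")
})

test_that("hit calling applies strict fold-change and p thresholds per readout", {
  st <- data.frame(plate_id = "P01", well = sprintf("A%02d", 1:5),
                   clone_id = letters[1:5], role = "sample", n = 20,
                   fc = c(0.5, 1.0, 0.66, 1.6, 0.84),
                   p_adj = c(1e-5, 1e-5, 1e-5, 1e-4, 0.5),
                   p_anova = 1e-6, stringsAsFactors = FALSE)
  hits <- call_hits(st, screen_config(), "reporter")
  expect_equal(hits$category, c("down", "none", "none", "up", "none"))
  size_hits <- call_hits(st, screen_config(), "size")
  expect_equal(size_hits$category, c("down", "none", "down", "none", "down"))
  # boundary FC exactly 0.85 is not a size hit
  st$fc[5] <- 0.85
  expect_equal(call_hits(st, screen_config(), "size")$category[5], "none")
})

test_that("library layout arithmetic matches the plate counts", {
  expect_equal(layout_library(6315)$n_plates, 72)
  expect_equal(layout_library(1207)$n_plates, 14)
  expect_equal(layout_library(0)$n_plates, 0)
  lay <- layout_library(90)
  expect_equal(lay$usable_wells_per_plate, 88)
  expect_equal(lay$manifest$well[1:9],
               c(sprintf("%s01", LETTERS[1:8]), "A02"))  # column-major fill
  expect_equal(max(lay$manifest$plate), 2)
})

test_that("sequencing QC reports the reliability percentage", {
  r <- library_qc_report(144, 131)
  expect_equal(r$percent_rounded, 91L)
  expect_equal(r$fraction, 131 / 144)
  expect_equal(library_qc_report(10, 10)$percent, 100)
  expect_equal(library_qc_report(200, 150)$percent, 75)
  expect_error(library_qc_report(10, 11), "n_correct")
})

test_that("plate maps without enough negative controls are rejected", {
  map <- default_plate_map(1, n_sample_wells = 4)
  bad <- map[!(map$role == "control_neg" & map$well %in% c("A12", "B12")), ]
  expect_error(validate_plate_map(bad), "negative-control")
})
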