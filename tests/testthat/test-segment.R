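# Well mask, worm segmentation, filtering, green heads, dilation, linking.

test_that("well mask matches the phantom ring geometry", {
  w <- std_well()
  wm <- w$seg$well_mask
  analytic <- pi * (0.92 * 256)^2
  expect_lt(abs(sum(wm) - analytic) / analytic, 0.02)
  # single connected region
  expect_equal(max(EBImage::bwlabel(wm)), 1)
  # every truth-worm pixel lies inside the well mask
  expect_true(all(wm[w$ph$truth$label_image > 0]))
})

test_that("a ringless green image falls back to a full-frame mask with a warning", {
  flat <- matrix(100L, 128, 128)
  expect_warning(wm <- segment_well(flat), "full-frame")
  expect_true(all(wm))
})

test_that("disjoint worms are recovered with high overlap and no spurious objects", {
  w <- std_well()
  expect_equal(max(w$seg$worm_labels), 4)
  m <- match_to_truth(w$seg, w$ph$truth)
  expect_true(all(m$jaccard >= 0.7))
  expect_setequal(m$truth_worm, 1:4)
  expect_equal(nrow(w$seg$excluded), 0)
  # uniform brightfield yields no candidates
  wm <- matrix(TRUE, 128, 128)
  cand <- segment_worms(matrix(30000L, 128, 128), wm, seg_config())
  expect_equal(max(cand), 0)
})

test_that("segmentation is deterministic for identical image and config", {
  ph <- generate_well_image(2, 0, seed = 31)
  s1 <- segment_well_set(ph$images)
  s2 <- segment_well_set(ph$images)
  expect_identical(s1$worm_labels, s2$worm_labels)
  expect_identical(s1$head_labels, s2$head_labels)
})

test_that("fibres, bubbles and overlapping pairs are excluded with reasons", {
  ph <- generate_well_image(2, 0,
                            artifacts = list(fibres = 1, bubbles = 1,
                                             overlaps = 1), seed = 3)
  seg <- segment_well_set(ph$images)
  expect_gt(nrow(seg$excluded), 0)
  # the two clean worms survive
  m <- match_to_truth(seg, ph$truth)
  clean <- ph$truth$worms$worm[!ph$truth$worms$artifact]
  expect_true(all(clean %in% m$truth_worm))
  # thin fibre: sub-minimal area; crossing pair: one blob, over-long skeleton
  expect_true("area_below" %in% seg$excluded$reason)
  expect_true(any(seg$excluded$reason %in% c("length_above", "area_above")))
  # no accepted object corresponds to the overlapping pair
  ovl <- ph$truth$worms$worm[ph$truth$worms$artifact]
  expect_false(any(m$truth_worm %in% ovl))
})

test_that("compact blobs violate the form-factor bound and border objects can be dropped", {
  lab <- matrix(0L, 120, 120)
  lab[40:80, 40:80][(row(matrix(0, 41, 41)) - 21)^2 +
                      (col(matrix(0, 41, 41)) - 21)^2 <= 20^2] <- 1L
  res <- filter_objects(lab, seg_config(area_range_px = c(100, 1e5),
                                        length_range_um = c(0, 1e5)),
                        pixel_size = 6.5)
  expect_equal(nrow(res$objects), 0)
  expect_equal(res$excluded$reason, "form_factor")

  lab2 <- matrix(0L, 120, 120)
  lab2[1:3, 10:100] <- 1L   # touches the border
  res2 <- filter_objects(lab2, seg_config(area_range_px = c(100, 1e5),
                                          length_range_um = c(0, 1e5)),
                         pixel_size = 6.5)
  expect_equal(res2$excluded$reason, "border")
})

test_that("green heads flag heterozygotes and require pixel overlap to link", {
  w <- std_well()
  truth <- w$ph$truth$worms
  m <- match_to_truth(w$seg, w$ph$truth)
  heads <- w$seg$objects$green_head_id
  for (k in seq_len(nrow(m))) {
    geno <- truth$genotype[truth$worm == m$truth_worm[k]]
    expect_identical(heads[k] > 0, geno == "heterozygote")
  }
  # an all-homozygote well has zero head counts
  ph0 <- generate_well_image(3, 0, seed = 19)
  s0 <- segment_well_set(ph0$images)
  expect_true(all(s0$objects$green_head_id == 0))
})

test_that("one-pixel overlap links a head; a detached blob is dropped with a warning", {
  worms <- matrix(0L, 60, 60)
  worms[10:40, 20:26] <- 1L
  green <- matrix(100L, 60, 60)
  green[40:45, 22:24] <- 5000L      # overlaps the worm in exactly one row
  cfg <- seg_config(head_area_px = c(5, 600), head_abs_threshold = 1000)
  h <- detect_green_heads(green, worms, cfg)
  expect_equal(h$head_worm, 1L)
  expect_equal(h$head_count, 1L)
  # head pixels are clipped into the worm
  expect_true(all(worms[h$labels > 0] == 1L))

  green2 <- matrix(100L, 60, 60)
  green2[42:45, 22:24] <- 5000L     # one pixel away from the worm
  expect_warning(h2 <- detect_green_heads(green2, worms, cfg),
                 "overlaps no worm")
  expect_equal(h2$head_count, 0L)
})

test_that("background rings exclude worms, neighbours and the well exterior", {
  w <- std_well()
  seg <- w$seg
  for (k in seq_len(max(seg$worm_labels))) {
    ring <- seg$rings[[k]]
    expect_gt(length(ring), 0)
    expect_true(all(seg$worm_labels[ring] == 0))
    expect_true(all(seg$well_mask[ring]))
  }
  # two adjacent bars: each ring avoids the neighbour's pixels
  lab <- matrix(0L, 60, 60)
  lab[10:50, 20:24] <- 1L
  lab[10:50, 28:32] <- 2L
  bg <- dilate_background(lab, seg_config(dilation_radius = 5,
                                          dilation_gap = 1))
  expect_true(all(lab[bg$rings[[1]]] == 0))
  expect_true(all(lab[bg$rings[[2]]] == 0))
  expect_false(bg$empty_ring[1] || bg$empty_ring[2])
})

test_that("mask-algebra invariants hold on a segmented phantom", {
  expect_mask_invariants(std_well()$seg)
})

test_that("the morphological skeleton measures elongated objects sensibly", {
  bar <- matrix(FALSE, 120, 30)
  bar[11:110, 13:17] <- TRUE   # 100 x 5 bar
  len <- wormscreen:::skeleton_length_px(wormscreen:::skeletonize(bar))
  expect_lt(abs(len - 100) / 100, 0.12)
})
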