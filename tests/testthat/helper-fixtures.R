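# Shared fixtures and independent oracles used across test files.

# One standard phantom well (3 homozygotes + 1 heterozygote) segmented once
# and reused; computed lazily and cached for the session.
std_well <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_well_image(3, 1, seed = 7)
      seg <- segment_well_set(ph$images)
      cache <<- list(ph = ph, seg = seg,
                     records = measure_worms(seg, ph$images))
    }
    cache
  }
})

# Map each accepted segmented object to the truth worm it overlaps most, with
# the Jaccard index of the match.
match_to_truth <- function(seg, truth) {
  tl <- truth$label_image
  n <- max(seg$worm_labels)
  out <- data.frame(seg_label = seq_len(n), truth_worm = NA_integer_,
                    jaccard = 0)
  for (k in seq_len(n)) {
    px <- which(seg$worm_labels == k)
    ov <- tl[px]; ov <- ov[ov > 0]
    if (!length(ov)) next
    tk <- as.integer(names(which.max(table(ov))))
    tpx <- which(tl == tk)
    out$truth_worm[k] <- tk
    out$jaccard[k] <- length(intersect(px, tpx)) / length(union(px, tpx))
  }
  out
}

# Assert the mask-algebra invariants of a segmentation result.
expect_mask_invariants <- function(seg) {
  n <- max(seg$worm_labels)
  # accepted and excluded labels are disjoint object sets by construction;
  # check the per-worm region algebra
  expect_true(all(seg$head_labels[seg$worm_labels == 0] == 0))
  for (k in seq_len(n)) {
    worm <- which(seg$worm_labels == k)
    heads <- which(seg$head_labels > 0 & seg$worm_labels == k)
    nohead <- which(seg$worm_minus_head_labels == k)
    expect_setequal(union(nohead, heads), worm)
    expect_length(intersect(seg$rings[[k]], worm), 0)
    expect_true(all(seg$well_mask[seg$rings[[k]]]))
    dil <- which(seg$dilated_labels == k)
    # the worm's own dilated region covers it except where an earlier label's
    # dilation claimed the raster cell; the ring+core set always covers it
    expect_true(all(worm %in% union(dil, which(seg$dilated_labels > 0))))
  }
}

# Independent Monte-Carlo oracle for Dunnett many-to-one adjusted p-values:
# simulates the null distribution of max |t_j| for a balanced one-way layout
# with a shared control, in chunks, and returns P(max|T| >= |t_obs|).
# Observed statistics are computed from first principles (no aov/glht).
dunnett_mc_oracle <- function(groups, n_sims = 1e6, seed = 42,
                              chunk = 50000L) {
  y <- unlist(groups)
  sizes <- lengths(groups)
  k <- length(groups) - 1L          # comparisons vs groups[[1]] (control)
  N <- sum(sizes)
  df <- N - length(groups)
  means <- vapply(groups, mean, numeric(1))
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  sp <- sqrt(ss / df)
  t_obs <- (means[-1] - means[1]) / (sp * sqrt(1 / sizes[-1] + 1 / sizes[1]))
  set.seed(seed)
  exceed <- numeric(k)
  done <- 0L
  while (done < n_sims) {
    b <- min(chunk, n_sims - done)
    gm <- matrix(NA_real_, b, length(groups))
    gss <- matrix(NA_real_, b, length(groups))
    for (j in seq_along(groups)) {
      x <- matrix(stats::rnorm(b * sizes[j]), sizes[j], b)
      gm[, j] <- colMeans(x)
      gss[, j] <- colSums(x^2) - sizes[j] * gm[, j]^2
    }
    spc <- sqrt(rowSums(gss) / df)
    tmax <- rep(0, b)
    for (j in 2:length(groups)) {
      tj <- abs(gm[, j] - gm[, 1]) / (spc * sqrt(1 / sizes[j] + 1 / sizes[1]))
      tmax <- pmax(tmax, tj)
    }
    for (j in seq_len(k))
      exceed[j] <- exceed[j] + sum(tmax >= abs(t_obs[j]))
    done <- done + b
  }
  list(t_obs = t_obs, p_adj = exceed / n_sims)
}

# Frozen 3-well fixture (pooled control + two sample wells, 10 worms each)
# for the Dunnett cross-check: normalized GFP values.
dunnett_fixture <- list(
  control = c(0.93, 1.08, 1.01, 0.89, 1.12, 0.97, 1.04, 0.95, 1.06, 0.99),
  well_A  = c(0.88, 0.97, 0.84, 1.02, 0.91, 0.79, 0.95, 0.87, 0.93, 0.90),
  well_B  = c(1.02, 0.95, 1.10, 0.99, 1.06, 0.93, 1.08, 1.01, 0.97, 1.04))

# Build a per-worm record table directly (hand fixtures for the filters).
worm_rows <- function(plate = "P01", well, n, value = 300, length_um = 900,
                      head = 0, clone = "cloneX", role = "sample") {
  data.frame(plate_id = plate, well = well, clone_id = clone, role = role,
             worm = seq_len(n),
             int_worm_minus_bkgd_green = rep_len(value, n),
             length_um = rep_len(length_um, n),
             green_head_id = rep_len(head, n), stringsAsFactors = FALSE)
}
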