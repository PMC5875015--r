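# Profiler features and the gating/accept rule.

test_that("profile features match brute-force counts of super-threshold samples", {
  p0 <- flow_profile(rep(0, 3), rep(0, 3))
  f0 <- profile_features(p0, green_floor = 700)
  expect_equal(f0$green_ph, 0)
  expect_equal(f0$green_pw, 0)

  g <- c(rep(0, 20), rep(800, 150), rep(0, 20))
  p1 <- flow_profile(rep(5000, length(g)), g)
  f1 <- profile_features(p1, green_floor = 700)
  expect_equal(f1$green_ph, 800)
  expect_equal(f1$green_pw, sum(g > 700))
  expect_equal(f1$green_pw, 150)

  # widths are integrated over all super-threshold areas, not one peak
  g2 <- c(rep(900, 60), rep(0, 30), rep(900, 60))
  p2 <- flow_profile(rep(5000, length(g2)), g2)
  expect_equal(profile_features(p2, green_floor = 700)$green_pw, 120)

  expect_error(flow_profile(numeric(0), numeric(0)), "at least one")
})

test_that("extinction gate uses closed boundaries", {
  cfg <- gate_config(ext_ph = c(2000, 60000), ext_pw = c(60, 1000))
  centre <- list(ext_ph = 20000, ext_pw = 150)
  expect_true(gate_extinction(centre, cfg))
  expect_false(gate_extinction(list(ext_ph = 20000, ext_pw = 0), cfg))
  # points exactly on the boundary are inside (closed-region convention)
  expect_true(gate_extinction(list(ext_ph = 2000, ext_pw = 60), cfg))
  expect_true(gate_extinction(list(ext_ph = 60000, ext_pw = 1000), cfg))
})

test_that("green classification follows the PH window and PW rule with ordered reasons", {
  cfg <- gate_config()
  mk <- function(ph, pw) list(green_ph = ph, green_pw = pw, green_peaks = 1)
  d <- classify_green(mk(12000, 10), cfg)   # pharyngeal signal
  expect_false(d$accepted)
  expect_equal(d$reason, "ph_above")
  expect_equal(classify_green(mk(0, 0), cfg)$reason, "ph_below")
  expect_equal(classify_green(mk(800, 100), cfg)$reason, "pw_below")
  a <- classify_green(mk(800, 150), cfg)
  expect_true(a$accepted)
  expect_equal(a$reason, "pass")
  # boundaries: PH bounds inclusive, PW strictly greater
  expect_true(classify_green(mk(700, 121), cfg)$accepted)
  expect_true(classify_green(mk(10000, 121), cfg)$accepted)
  expect_false(classify_green(mk(800, 120), cfg)$accepted)
})

test_that("classification agrees with direct rule evaluation on random features", {
  cfg <- gate_config()
  set.seed(99)
  for (i in 1:1000) {
    ph <- stats::runif(1, 0, 20000)
    pw <- sample(0:300, 1)
    got <- classify_green(list(green_ph = ph, green_pw = pw), cfg)$accepted
    want <- ph >= 700 && ph <= 10000 && pw > 120
    expect_identical(got, want)
  }
})

test_that("tightening the width or height window never grows the accepted set", {
  set.seed(17)
  feats <- lapply(1:200, function(i)
    list(green_ph = stats::runif(1, 0, 15000), green_pw = sample(0:300, 1)))
  acc <- function(cfg) vapply(feats, function(f)
    classify_green(f, cfg)$accepted, logical(1))
  base <- acc(gate_config())
  expect_true(all(acc(gate_config(green_pw_min = 150)) <= base))
  wide <- acc(gate_config(green_ph_lo = 500, green_ph_hi = 12000))
  expect_true(all(wide >= base))
})

test_that("population sorting reports efficiency against ground truth", {
  g <- generate_flow_profiles(50, 50, 0, noise_cv = 0, seed = 21)
  res <- sort_population(g$profiles, gate_config(), truth = g$truth$class)
  expect_equal(res$report$efficiency, 1.0)
  expect_equal(res$report$false_accept, 0)

  deb <- generate_flow_profiles(0, 0, 30, noise_cv = 0.1, seed = 22)
  rd <- sort_population(deb$profiles, gate_config(), truth = deb$truth$class)
  expect_equal(sum(rd$decisions$accepted), 0)
  expect_true(all(rd$decisions$reason == "ext_gate_fail"))

  expect_error(sort_population(g$profiles, gate_config(), truth = "x"),
               "truth length")
  expect_error(sort_population(list(), gate_config()), "non-empty")
})

test_that("heterozygote profiles show the two-lobed pharynx in the peak diagnostic", {
  g <- generate_flow_profiles(0, 10, 0, noise_cv = 0, seed = 5)
  res <- sort_population(g$profiles, gate_config())
  expect_true(all(res$decisions$green_peaks >= 2))
})
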