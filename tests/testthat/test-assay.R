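test_that("runoff fit is exact on noiseless courses", {
  t <- c(5, 10, 20, 40)
  y <- 0.9 * (1 - exp(-0.1 * t))
  fit <- fit_runoff_exponential(runoff_course(t, y))
  expect_equal(fit$k, 0.1, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.9, tolerance = 1e-6)
  expect_lt(fit$residual_ss, 1e-8)
  expect_false(fit$flagged)

  # amplitude can be pinned at 1
  y1 <- 1 - exp(-0.07 * t)
  fit1 <- fit_runoff_exponential(runoff_course(t, y1), fix_amplitude = TRUE)
  expect_equal(fit1$k, 0.07, tolerance = 1e-8)
  expect_equal(fit1$amplitude, 1)
})

test_that("degenerate courses are flagged, not silently fit", {
  z <- fit_runoff_exponential(runoff_course(c(5, 10, 20, 40), rep(0, 4)))
  expect_true(z$flagged)
  expect_error(fit_runoff_exponential(runoff_course(c(5, 10), c(0.1, 0.2))),
               "3 time points")
  expect_error(runoff_course(c(5, 10, 20), c(0.2, 1.4, 0.5)), "\\[0, 1\\]")
})

test_that("Monte-Carlo calibration: rate recovery and SE coverage", {
  true_k <- 0.1
  reps <- 200L
  khat <- numeric(reps)
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_assay(assay_sim_params(true_k = true_k, amplitude = 0.9,
                                           noise_sigma = 0.02,
                                           replicates = 1L, seed = r))
    fit <- fit_runoff_exponential(sim$runoff[[1L]])
    khat[r] <- fit$k
    covered[r] <- abs(fit$k - true_k) <= fit$se_k
  }
  expect_equal(mean(khat), true_k, tolerance = 0.05)
  # 68% asymptotic intervals should cover at roughly their nominal rate
  expect_gte(mean(covered), 0.60)
  expect_lte(mean(covered), 0.80)
})

test_that("relative elongation rates propagate errors sensibly", {
  t <- c(5, 10, 20, 40)
  wt <- fit_runoff_exponential(runoff_course(t, 0.9 * (1 - exp(-0.1 * t))))
  expect_equal(relative_elongation_rate(wt, wt)$ratio, 1.0, tolerance = 1e-9)
  mut <- fit_runoff_exponential(runoff_course(t, 0.9 * (1 - exp(-0.2 * t))))
  expect_equal(relative_elongation_rate(mut, wt)$ratio, 2.0,
               tolerance = 1e-6)
  zero <- wt; zero$k <- 0
  expect_error(relative_elongation_rate(mut, zero), "zero")

  # noisy fast-mutant scenario: planted ratio 1.5 recovered across seeds
  ratios <- vapply(1:20, function(sd0) {
    simw <- simulate_assay(assay_sim_params(true_k = 0.1, replicates = 1L,
                                            noise_sigma = 0.02, seed = sd0))
    simm <- simulate_assay(assay_sim_params(true_k = 0.15, replicates = 1L,
                                            noise_sigma = 0.02,
                                            seed = sd0 + 1000L))
    fw <- fit_runoff_exponential(simw$runoff[[1L]])
    fm <- fit_runoff_exponential(simm$runoff[[1L]])
    relative_elongation_rate(fm, fw)$ratio
  }, numeric(1L))
  expect_equal(mean(ratios), 1.5, tolerance = 0.1)
})

test_that("misincorporation ratio reads competition bands", {
  expect_equal(misincorporation_ratio(
    band_table("L1", c(G10 = 500, A10 = 0)))$error_fraction, 0)
  expect_equal(misincorporation_ratio(
    band_table("L2", c(G10 = 300, A10 = 300)))$error_fraction, 0.5)
  both0 <- misincorporation_ratio(band_table("L3", c(G10 = 0, A10 = 0)))
  expect_true(both0$flagged)
  expect_true(is.na(both0$error_fraction))
  expect_equal(misincorporation_ratio(
    band_table("L4", c(G10 = 900, A10 = 100)),
    display = "complement")$display_value, 0.9)

  # planted 10% misincorporation with noise recovered within 0.02
  fr <- vapply(1:30, function(sd0) {
    sim <- simulate_assay(assay_sim_params(misincorporation_p = 0.1,
                                           replicates = 1L, seed = sd0))
    misincorporation_ratio(sim$fidelity[[1L]])$error_fraction
  }, numeric(1L))
  expect_equal(mean(fr), 0.1, tolerance = 0.02 / 0.1)

  # scale invariance under a global intensity factor
  a <- misincorporation_ratio(band_table("s", c(G10 = 321, A10 = 47)))
  b <- misincorporation_ratio(band_table("s", c(G10 = 321 * 7.3,
                                                A10 = 47 * 7.3)))
  expect_equal(a$error_fraction, b$error_fraction)
})

test_that("translocation-state fractions normalise and scale-invariate", {
  expect_equal(translocation_state_fractions(
    band_table("x", c(pre = 75, post = 25))), c(pre = 0.75, post = 0.25))
  expect_equal(translocation_state_fractions(
    band_table("x", c(pre = 40, post = 40))), c(pre = 0.5, post = 0.5))
  expect_error(translocation_state_fractions(
    band_table("x", c(pre = 0, post = 0))), "zero")
  f1 <- translocation_state_fractions(band_table("x", c(pre = 30, post = 62)))
  f2 <- translocation_state_fractions(band_table("x", c(pre = 300, post = 620)))
  expect_equal(f1, f2)

  # planted triplicates around (0.49, 0.51)
  posts <- vapply(1:30, function(sd0) {
    sim <- simulate_assay(assay_sim_params(post_without = 0.51,
                                           replicates = 1L, seed = sd0))
    translocation_state_fractions(sim$exo3[[1L]]$without)[["post"]]
  }, numeric(1L))
  expect_equal(mean(posts), 0.51, tolerance = 0.02 / 0.51)
})

test_that("NTP stimulation folds multiply and handle the worked example", {
  st <- ntp_stimulation(0.25, 0.51)
  expect_equal(st$fold, 2.04, tolerance = 1e-9)
  expect_equal(st$percent_increase, 104, tolerance = 1e-9)
  expect_equal(ntp_stimulation(0.4, 0.4)$fold, 1.0)
  expect_equal(ntp_stimulation(0.4, 0.4)$percent_increase, 0)
  expect_error(ntp_stimulation(0, 0.5), "positive")

  # sequential stimulations compose multiplicatively
  f1 <- ntp_stimulation(0.2, 0.3)$fold
  f2 <- ntp_stimulation(0.3, 0.45)$fold
  expect_equal(ntp_stimulation(0.2, 0.45)$fold, f1 * f2, tolerance = 1e-12)
})

test_that("assay tables round trip through delimited text", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("enzyme\ttime_s\tfraction",
               "WT\t5\t0.35", "WT\t10\t0.55", "WT\t20\t0.78", "WT\t40\t0.88",
               "mut\t5\t0.10", "mut\t10\t0.22", "mut\t20\t0.40",
               "mut\t40\t0.62"), tf)
  courses <- read_runoff_table(tf)
  expect_setequal(names(courses), c("WT", "mut"))
  expect_equal(nrow(courses$WT), 4L)
  fit <- fit_runoff_exponential(courses$WT)
  expect_false(fit$flagged)

  tb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lane\tband\tintensity",
               "wt_noNTP\tpre\t750", "wt_noNTP\tpost\t250",
               "wt_NTP\tpre\t490", "wt_NTP\tpost\t510"), tb)
  bands <- read_band_table(tb)
  fr <- translocation_state_fractions(bands$wt_noNTP)
  expect_equal(fr[["post"]], 0.25)
})
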