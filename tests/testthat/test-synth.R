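test_that("population_spec validates its parameters", {
  expect_error(population_spec("hind", icc = 1.2), "icc")
  expect_error(population_spec("hind", icc = -0.1), "icc")
  expect_error(population_spec("hind", year_drift_sd = -1), "non-negative")
  expect_s3_class(population_spec("calf"), "population_spec")
})

test_that("icc = 0 collapses all individuals onto one latent mean", {
  pop <- make_population(population_spec("hind", icc = 0), 5, seed = 1)
  lat <- sapply(pop$profiles, function(p) p$latent$oral)
  expect_true(all(apply(lat, 1, function(v) max(v) - min(v)) < 1e-12))
})

test_that("icc = 1 makes every call of an individual identical in latent parameters", {
  pop <- make_population(population_spec("hind", icc = 1), 3, seed = 2)
  ft <- sample_features_direct(pop, n_calls_per_type = 4, call_types = "oral",
                               seed = 3)
  for (id in unique(ft$individual_id)) {
    sub <- ft[ft$individual_id == id, "f0max"]
    expect_lt(max(sub) - min(sub), 1e-12)
  }
})

test_that("latent grand means match the reference population values", {
  ## 22 hinds as in the discriminant design; SE of the latent f0max grand
  ## mean is sqrt(icc) * 31 / sqrt(22) ~ 5.5 Hz
  pop <- make_population(population_spec("hind", icc = 0.7), 22, seed = 7)
  f0max <- sapply(pop$profiles, function(p) p$latent$oral[["f0max"]])
  expect_lt(abs(mean(f0max) - 180), 3 * sqrt(0.7) * 31 / sqrt(22))
  durat <- sapply(pop$profiles, function(p) p$latent$oral[["durat"]])
  expect_lt(abs(mean(durat) - 0.759), 3 * sqrt(0.7) * 0.235 / sqrt(22))
})

test_that("profile latents satisfy the contour ordering invariants", {
  for (cls in c("hind", "calf")) {
    pop <- make_population(population_spec(cls, icc = 0.7), 30, seed = 5)
    for (p in pop$profiles) for (ct in c("oral", "nasal")) {
      l <- p$latent[[ct]]
      expect_lte(l[["f0min"]], l[["f0beg"]])
      expect_lte(l[["f0beg"]], l[["f0max"]])
      expect_gt(l[["durat"]], l[["dur_to_max"]])
      expect_gte(l[["dur_to_max"]], 0)
    }
  }
})

test_that("variance decomposition recovers the configured icc", {
  icc <- 0.6
  pop <- make_population(population_spec("hind", icc = icc), 40, seed = 11)
  ft <- sample_features_direct(pop, n_calls_per_type = 25,
                               call_types = "oral", seed = 12)
  for (v in c("f0max", "durat", "q50")) {
    a <- anova(lm(ft[[v]] ~ factor(ft$individual_id)))
    msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
    s2b <- (msb - msw) / 25
    expect_lt(abs(s2b / (s2b + msw) - icc), 0.12)
  }
})

test_that("generation is deterministic under a fixed seed", {
  p1 <- make_population(population_spec("calf"), 4, seed = 31)
  p2 <- make_population(population_spec("calf"), 4, seed = 31)
  expect_identical(p1, p2)
  c1 <- synth_call(p1$profiles[[1]], "oral", seed = 8)
  c2 <- synth_call(p2$profiles[[1]], "oral", seed = 8)
  expect_identical(c1$wave$samples, c2$wave$samples)
  f1 <- sample_features_direct(p1, 3, "oral", seed = 9)
  f2 <- sample_features_direct(p2, 3, "oral", seed = 9)
  expect_identical(f1, f2)
})

test_that("synthesized waveform matches its ground-truth contour and duration", {
  pop <- small_population(n = 2)
  cl <- synth_call(pop$profiles[[1]], "oral", seed = 13)
  expect_equal(cl$offset - cl$onset, cl$params$durat, tolerance = 1e-6)
  ## extractor round trip against the generator's own contour
  ct <- extract_f0_contour(cl$wave, pitch_params("hind"),
                           onset = cl$onset, offset = cl$offset)
  truth <- approx(cl$contour$time, cl$contour$f0, xout = ct$time, rule = 2)$y
  rel <- abs(ct$f0[ct$voiced] - truth[ct$voiced]) / truth[ct$voiced]
  expect_lt(max(rel), 0.03)
})

test_that("a flat contour synthesizes to a call with near-zero delta_f0", {
  pop <- small_population(n = 1, icc = 0)
  pr <- pop$profiles[[1]]
  for (ct in c("oral", "nasal")) {
    pr$latent[[ct]][c("f0beg", "f0max", "f0min")] <- 200
    pr$within_sd[[ct]][] <- 0
  }
  cl <- synth_call(pr, "oral", seed = 14)
  ft <- extract_features(cl$wave, cl$meta, onset = cl$onset, offset = cl$offset)
  expect_lt(ft$delta_f0, 6)   # 3% of 200 Hz
  expect_equal(ft$f0max, 200, tolerance = 0.03 * 200)
})

test_that("invalid contour parameters raise a parameter error", {
  pop <- small_population(n = 1)
  pr <- pop$profiles[[1]]
  pr$latent$oral["f0beg"] <- pr$latent$oral["f0max"] + 100
  pr$within_sd$oral[] <- 0
  expect_error(synth_call(pr, "oral", seed = 1), "f0min <= f0beg <= f0max")
})

test_that("direct feature sampling matches spec marginals and warns on degenerate design", {
  pop <- make_population(population_spec("calf", icc = 0.5), 30, seed = 15)
  ft <- sample_features_direct(pop, 20, call_types = "nasal", seed = 16)
  ref <- reference_call_params("calf", "nasal")
  for (v in c("f0max", "durat", "q25", "power_f0")) {
    se <- ref["sd", v] / sqrt(30)  # individual-level sampling error dominates
    expect_lt(abs(mean(ft[[v]]) - ref["mean", v]), 4 * se)
    expect_lt(abs(sd(ft[[v]]) / ref["sd", v] - 1), 0.35)
  }
  expect_warning(sample_features_direct(pop, 1, "oral", seed = 1), ">= 2")
  expect_error(sample_features_direct(pop, 0, "oral"), "positive")
})

test_that("gaussian null table has the requested design and is reproducible", {
  sizes <- sample_group_sizes(22, 5, 10, 209, seed = 17)
  expect_length(sizes, 22)
  expect_equal(sum(sizes), 209)
  expect_true(all(sizes >= 5 & sizes <= 10))
  tab <- gaussian_null_table(sizes, 11, seed = 18)
  expect_equal(nrow(tab), 209)
  expect_equal(length(unique(tab$individual_id)), 22)
  expect_equal(ncol(tab), 12)
  tab2 <- gaussian_null_table(sizes, 11, seed = 18)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f1, row.names = FALSE); write.csv(tab2, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(gaussian_null_table(c(1, 5), 3), "at least 2")
  expect_error(sample_group_sizes(5, 5, 10, 200), "infeasible")
})

test_that("year drift shifts latent means by the configured scale", {
  pop <- make_population(population_spec("hind", icc = 0.7), 40, seed = 19)
  drifted <- drift_population(pop, year_drift_sd = 1, seed = 20)
  d <- sapply(seq_along(pop$profiles), function(i)
    drifted$profiles[[i]]$latent$oral[["q50"]] -
      pop$profiles[[i]]$latent$oral[["q50"]])
  ref_sd <- reference_call_params("hind", "oral")["sd", "q50"]
  expect_lt(abs(sd(d) / ref_sd - 1), 0.45)  # 40 draws of N(0, sd^2)
  same <- drift_population(pop, year_drift_sd = 0, seed = 21)
  expect_equal(same$profiles[[1]]$latent$oral, pop$profiles[[1]]$latent$oral)
})
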