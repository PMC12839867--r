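test_that("default study specs encode the eight regions and subgroups", {
  specs <- default_study_specs()
  expect_length(specs$regions, 8L)
  expect_length(specs$subgroups, 8L)
  js <- Filter(function(s) s$region == "Jiangsu", specs$regions)[[1]]
  expect_equal(js$classes$SCCP$mean, 497.6)
  expect_equal(js$classes$SCCP$range, c(32.1, 1542.4))
  expect_equal(sum(vapply(specs$subgroups, `[[`, integer(1),
                          "n_individuals")), 55678L)
  for (s in specs$regions) {
    for (cl in names(s$classes)) {
      p <- s$classes[[cl]]
      expect_true(p$mean >= p$range[1] && p$mean <= p$range[2])
      expect_equal(sum(p$profile$fraction), 1, tolerance = 1e-12)
      expect_true(all(p$profile$fraction >= 0))
    }
  }
})

test_that("default congener profiles sit inside the reported bands", {
  ps <- default_congener_profile("SCCP")
  c10 <- sum(ps$fraction[ps$carbon == 10])
  c11 <- sum(ps$fraction[ps$carbon == 11])
  cl6 <- sum(ps$fraction[ps$chlorine == 6])
  cl7 <- sum(ps$fraction[ps$chlorine == 7])
  expect_gt(c10, 0.29); expect_lt(c10, 0.63)
  expect_gt(c11, 0.22); expect_lt(c11, 0.29)
  expect_gt(cl6, 0.23); expect_lt(cl6, 0.55)
  expect_gt(cl7, 0.22); expect_lt(cl7, 0.34)
  pm <- default_congener_profile("MCCP")
  c1415 <- sum(pm$fraction[pm$carbon %in% 14:15])
  expect_gt(c1415, 0.58); expect_lt(c1415, 0.66)
})

test_that("infeasible or malformed region specs are rejected", {
  prof <- default_congener_profile("SCCP")
  expect_error(
    region_conc_spec("X", 5, list(SCCP = list(mean = 5, range = c(10, 20),
                                              profile = prof))),
    "infeasible"
  )
  bad <- prof; bad$fraction <- bad$fraction * 2
  expect_error(
    region_conc_spec("X", 5, list(SCCP = list(mean = 15, range = c(10, 20),
                                              profile = bad))),
    "sum to 1"
  )
})

test_that("concentration generation is seed-reproducible and exact in totals", {
  spec <- default_study_specs()$regions[[4]]  # Tianjin, n = 7
  a <- gen_concentrations(spec, seed = 123)
  b <- gen_concentrations(spec, seed = 123)
  d <- gen_concentrations(spec, seed = 124)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$conc_ng_g, d$conc_ng_g)))

  # per-class total equals the sum of its 24 congeners exactly, and lies
  # inside the target range
  for (cl in c("SCCP", "MCCP")) {
    p <- spec$classes[[cl]]
    for (sid in unique(a$sample_id)) {
      v <- a$conc_ng_g[a$sample_id == sid & a$analyte_class == cl]
      expect_length(v, 24L)
      tot <- sum(v)
      expect_gte(tot, p$range[1])
      expect_lte(tot, p$range[2])
    }
  }
  # adding a region does not perturb an existing region's substream
  both <- gen_concentrations(default_study_specs()$regions[c(4, 5)],
                             seed = 123)
  expect_identical(both$conc_ng_g[both$region == "Tianjin"], a$conc_ng_g)
})

test_that("infinite profile dispersion degenerates to the mean profile", {
  prof <- default_congener_profile("SCCP")
  spec <- region_conc_spec("X", 3, list(
    SCCP = list(mean = 100, range = c(10, 1000), profile = prof)
  ), profile_dispersion = Inf)
  g <- gen_concentrations(spec, seed = 1)
  for (sid in unique(g$sample_id)) {
    v <- g$conc_ng_g[g$sample_id == sid]
    expect_equal(v / sum(v), prof$fraction, tolerance = 1e-12)
  }
})

test_that("generated class-total mean approaches the regional target", {
  spec <- default_study_specs()$regions[[1]]  # Jilin: SCCP mean 99.7
  spec$n_samples <- 10000L
  g <- gen_concentrations(spec, seed = 2024)
  tot <- class_totals(g)
  m <- mean(tot$total_ng_g[tot$analyte_class == "SCCP"])
  expect_lt(abs(m - 99.7) / 99.7, 0.05)
})

test_that("lognormal parameters are recovered from untruncated draws", {
  sdlog <- 0.5; mean <- 100
  meanlog <- log(mean) - sdlog^2 / 2
  spec <- untruncated_spec(n = 10000, mean = mean, sdlog = sdlog)
  tot <- class_totals(gen_concentrations(spec, seed = 77))
  fit <- fit_distribution(tot$total_ng_g[tot$analyte_class == "SCCP"],
                          families = "lognormal")
  n <- 10000
  expect_lt(abs(fit$estimate[["meanlog"]] - meanlog), 3 * sdlog / sqrt(n))
  expect_lt(abs(fit$estimate[["sdlog"]] - sdlog), 3 * sdlog / sqrt(2 * n))
})

test_that("range truncation shrinks the refitted log-sd as theory predicts", {
  # central-99% truncation of a normal shrinks its sd by factor
  # sqrt(1 - 2 c phi(c) / (2 Phi(c) - 1)), c = qnorm(0.995): ~0.9615
  c0 <- qnorm(0.995)
  shrink <- sqrt(1 - 2 * c0 * dnorm(c0) / (2 * pnorm(c0) - 1))
  sdlog <- 0.5; mean <- 100
  meanlog <- log(mean) - sdlog^2 / 2
  range <- exp(meanlog + c(-1, 1) * c0 * sdlog)  # symmetric in log space
  spec <- region_conc_spec("X", 10000, list(
    SCCP = list(mean = mean, range = range,
                profile = default_congener_profile("SCCP"))
  ))
  tot <- class_totals(gen_concentrations(spec, seed = 88))
  fit <- fit_distribution(tot$total_ng_g, families = "lognormal")
  expect_equal(fit$estimate[["sdlog"]] / sdlog, shrink, tolerance = 0.02)
})

test_that("survey generation honors degenerate consumption settings", {
  base <- function(p, meanlog, sdlog = 0) {
    subgroup_cons_spec("18-59 male", "male", 18, 60, 200,
                       consumer_probability = p,
                       amount_meanlog = meanlog, amount_sdlog = sdlog,
                       bw_meanlog = log(66), bw_sdlog = 0.15)
  }
  s1 <- assign_subgroups(gen_survey(base(1, log(54.7)), seed = 3))
  expect_true(all(s1$consumer_only))
  expect_equal(s1$mean_consumption, rep(54.7, 200), tolerance = 1e-12)
  s0 <- assign_subgroups(gen_survey(base(0, log(54.7)), seed = 3))
  expect_true(all(s0$mean_consumption == 0))
  expect_false(any(s0$consumer_only))
})

test_that("survey generation is seed-reproducible and order-stable", {
  specs <- default_study_specs(survey_scale = 0.005)$subgroups
  a <- gen_survey(specs, seed = 9)
  b <- gen_survey(specs, seed = 9)
  expect_identical(a, b)
  solo <- gen_survey(specs[[3]], seed = 9)
  expect_identical(solo$body_weight,
                   a$body_weight[a$age >= 13 & a$age < 18 & a$sex == "male"])
})

test_that("calibrated defaults hit the pooled consumption target", {
  # full-size default world (~55,678 individuals): pooled mean daily
  # consumption within 10% of 16.8 g/d, consumer-only mean near 54.7 g/d
  survey <- gen_survey(default_study_specs()$subgroups, seed = 31)
  expect_lt(abs(mean(survey$mean_consumption) - 16.8) / 16.8, 0.10)
  a <- assign_subgroups(survey)
  co <- a$mean_consumption[a$consumer_only]
  expect_lt(abs(mean(co) - 54.7) / 54.7, 0.10)
})
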