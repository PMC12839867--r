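test_that("regional summaries report detection, moments and flags", {
  conc <- toy_conc()
  s <- summarize_regions(conc)
  expect_s3_class(s, "cp_region_summary")
  # s1 Jilin SCCP total = 100.5, above the 3 ng/g MDL
  row <- s[s$region == "Jilin" & s$analyte_class == "SCCP", ]
  expect_equal(row$n, 1L)
  expect_equal(row$detection_rate, 1.0)
  expect_equal(row$mean, 100.5)
  expect_equal(row$min, row$max)
  expect_equal(row$sd, 0)
  expect_true(row$sd_flag)
  # Hebei MCCP total = 2.5 + 10 = 12.5 > 5 -> detected
  row2 <- s[s$region == "Hebei" & s$analyte_class == "MCCP", ]
  expect_equal(row2$n_detected, 1L)
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  expect_error(summarize_regions(conc[0, ]), "no concentration")
})

test_that("below-MDL totals count as non-detects", {
  f <- write_tmp_csv(c("sample_id,region,carbon,chlorine,conc_ng_g",
                       "s1,Tianjin,14,5,<MDL",
                       "s2,Tianjin,14,5,90.0"))
  s <- summarize_regions(read_concentrations(f, "middle"))
  expect_equal(s$n, 2L)
  expect_equal(s$n_detected, 1L)
  expect_equal(s$detection_rate, 0.5)
})

test_that("pooled mean is the sample-size-weighted regional mean", {
  s <- data.frame(analyte_class = "SCCP", n = c(10, 11, 8),
                  mean = c(21.5, 30.4, 497.6))
  expect_equal(round(pooled_mean(s), 1), 156.2)  # East China trio
  expect_equal(pooled_mean(s[1, ]), 21.5)        # single summary
  expect_error(pooled_mean(s[0, ]), "at least one")
  # equals the plain mean of the concatenated per-sample totals
  conc <- gen_concentrations(default_study_specs()$regions[4:5], seed = 6)
  tot <- class_totals(conc)
  summ <- summarize_regions(conc)
  for (cl in c("SCCP", "MCCP")) {
    expect_equal(pooled_mean(summ[summ$analyte_class == cl, ]),
                 mean(tot$total_ng_g[tot$analyte_class == cl]))
  }
})

test_that("Kruskal-Wallis H matches hand computation and base R", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(kw$statistic, 2.4)  # 12/(n(n+1)) * sum n_i (Rbar_i - (n+1)/2)^2
  expect_equal(kw$df, 1L)
  ident <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$raw_p, 1)

  set.seed(14)
  gs <- list(rnorm(12), rnorm(15, 0.5), round(rnorm(9), 1))  # with ties
  gs[[1]][1:2] <- gs[[2]][1:2]
  ref <- kruskal.test(gs)
  mine <- kruskal_wallis(gs)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$raw_p, ref$p.value)
})

test_that("exact permutation p matches brute-force enumeration", {
  # fully separated 4 + 4: H = 5.333, exact p = 2/70
  kw <- kruskal_wallis(list(1:4, 5:8))
  expect_false(is.na(kw$p_exact))
  expect_equal(kw$p_exact, 2 / 70)
  expect_lt(abs(kw$p_exact - kw$raw_p), 0.05)
  # three small groups: exact p in [0, 1], H unchanged by enumeration
  gs3 <- list(c(1.2, 3.4), c(0.3, 2.2, 5.1), c(4.4, 0.9, 2.9))
  kw3 <- kruskal_wallis(gs3)
  expect_false(is.na(kw3$p_exact))
  expect_gte(kw3$p_exact, 0)
  expect_lte(kw3$p_exact, 1)
  # above the exact-size cutoff no enumeration is attempted
  expect_true(is.na(kruskal_wallis(list(rnorm(20), rnorm(20)))$p_exact))
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(8)
  gs <- list(rlnorm(10), rlnorm(12, 0.4), rlnorm(7, -0.3))
  h0 <- kruskal_wallis(gs)$statistic
  expect_equal(kruskal_wallis(lapply(gs, log))$statistic, h0)
  expect_equal(kruskal_wallis(lapply(gs, function(x) x^3))$statistic, h0)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)             # single comparison
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))  # all equal
  set.seed(21)
  p <- runif(40)^2
  adj <- bh_adjust(p)
  expect_equal(adj, p.adjust(p, "BH"))  # independent reference
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))  # order-preserving
})

test_that("pairwise Wilcoxon tests cover all pairs with BH adjustment", {
  set.seed(4)
  gs <- list(a = rnorm(8), b = rnorm(8, 2), c = rnorm(8, 4))
  pw <- pairwise_wilcoxon_bh(gs)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$adjusted_p, bh_adjust(pw$raw_p))
  expect_true(all(pw$adjusted_p >= pw$raw_p))
  expect_true(all(pw$method == "wilcoxon-exact"))  # small, no ties
  ref <- wilcox.test(gs$a, gs$b, exact = TRUE)
  expect_equal(pw$raw_p[1], ref$p.value)
  expect_error(pairwise_wilcoxon_bh(list(a = 1:3, b = numeric(0))), "empty")
  # ties force the normal approximation
  gs2 <- list(a = c(1, 1, 2, 3), b = c(2, 2, 3, 4))
  expect_equal(pairwise_wilcoxon_bh(gs2)$method, "wilcoxon-normal")
})

test_that("correlation CIs follow the Fisher z transform", {
  # r = 0.5, n = 30: z = atanh(0.5), se = 1/sqrt(27)
  x <- seq_len(30)
  set.seed(10)
  y <- 0.5 * as.numeric(scale(x)) + sqrt(0.75) * rnorm(30)
  ct <- correlation_with_ci(x, y, "pearson")
  z <- atanh(ct$r); se <- 1 / sqrt(27)
  expect_equal(ct$ci_low, tanh(z - qnorm(0.975) * se))
  expect_equal(ct$ci_high, tanh(z + qnorm(0.975) * se))
  expect_equal(c(tanh(atanh(0.5) - qnorm(0.975) * se),
                 tanh(atanh(0.5) + qnorm(0.975) * se)),
               c(0.1704314, 0.7289586), tolerance = 1e-6)
  ref <- cor.test(x, as.numeric(y))
  expect_equal(ct$ci_low, unname(ref$conf.int[1]), tolerance = 1e-6)
  expect_equal(ct$p, ref$p.value)

  # spearman variance inflated by 1.06
  cs <- correlation_with_ci(x, as.numeric(y), "spearman")
  expect_lt(cs$ci_low, tanh(atanh(cs$r) - qnorm(0.975) * se))

  expect_equal(correlation_with_ci(1:10, (1:10)^3, "spearman")$r, 1)
  expect_true(correlation_with_ci(1:10, (1:10)^3, "spearman")$degenerate)
  expect_error(correlation_with_ci(rep(1, 10), 1:10), "zero variance")
  expect_error(correlation_with_ci(1:3, 1:3), "n >= 4")
})

test_that("independent draws give near-zero correlation at n = 10,000", {
  set.seed(17)
  x <- rnorm(10000); y <- rnorm(10000)
  expect_lt(abs(correlation_with_ci(x, y, "pearson")$r), 0.05)
  # pearson r on standardized data equals the covariance
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
  expect_equal(correlation_with_ci(xs, ys, "pearson")$r,
               cov(xs, ys), tolerance = 1e-12)
})

test_that("class correlations recover the generator's shared-total link", {
  conc <- gen_concentrations(default_study_specs()$regions[[1]], seed = 19)
  cc <- class_correlations(conc, "spearman")
  expect_true("Jilin" %in% cc$region)
  expect_true(all(cc$r >= -1 & cc$r <= 1))
  expect_true(all(cc$ci_low <= cc$r & cc$r <= cc$ci_high))
})
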