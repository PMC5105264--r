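phr_only <- function(...) {
  simulation_config(...,
    monomorphic_fraction = 0,
    category_fractions = c(PolyHighResolution = 1, NoMinorHom = 0,
                           MonoHighResolution = 0, OffTargetVariant = 0,
                           CallRateBelowThres = 0, Other = 0))
}

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simulation_config(n_samples = 0), class = "config_error")
  expect_error(simulation_config(error_rate_left = 0.6), class = "config_error")
  expect_error(simulation_config(missing_rate_right = 1), class = "config_error")
  expect_error(maf_point_mass(0.7), class = "config_error")
  # MonoHighResolution labels need a monomorphic pool to sit on
  expect_error(simulation_config(
    monomorphic_fraction = 0,
    category_fractions = c(PolyHighResolution = 0.9, NoMinorHom = 0,
                           MonoHighResolution = 0.1, OffTargetVariant = 0,
                           CallRateBelowThres = 0, Other = 0)),
    class = "config_error")
})

test_that("the truth model is Hardy-Weinberg with a seeded RNG", {
  cfg <- phr_only(n_samples = 40, n_snps = 50, seed = 6,
                  maf_law = maf_point_mass(0))
  t0 <- simulate_truth(cfg)
  expect_true(all(t0$true_calls == 0L))

  cfg5 <- phr_only(n_samples = 200, n_snps = 200, seed = 6,
                   maf_law = maf_point_mass(0.5))
  t5 <- simulate_truth(cfg5)
  n <- length(t5$true_calls)
  for (g in 0:2) {
    p <- c(0.25, 0.5, 0.25)[g + 1]
    obs <- mean(t5$true_calls == g)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }

  expect_identical(simulate_truth(cfg5)$true_calls, t5$true_calls)
  sim_a <- simulate_dual_platform(simulation_config(n_samples = 10, n_snps = 80, seed = 12))
  sim_b <- simulate_dual_platform(simulation_config(n_samples = 10, n_snps = 80, seed = 12))
  expect_identical(sim_a$pair$left$calls, sim_b$pair$left$calls)
  expect_identical(sim_a$pair$right$quality, sim_b$pair$right$quality)
  expect_identical(sim_a$truth$category, sim_b$truth$category)
})

test_that("zero error reproduces the truth; the kernel gives exact flip rates", {
  cfg <- phr_only(n_samples = 30, n_snps = 100, seed = 19,
                  error_rate_left = 0, error_rate_right = 0,
                  missing_rate_left = 0, missing_rate_right = 0)
  truth <- simulate_truth(cfg)
  left <- apply_platform_error(truth, "left", cfg)
  expect_identical(unname(left$calls), truth$true_calls)

  K <- allele_error_kernel(0.01)
  expect_equal(K["0", "1"], 2 * 0.01 * 0.99)
  expect_equal(K["0", "2"], 1e-4)
  expect_equal(unname(rowSums(K)), rep(1, 3))
  # independent closed form for the heterozygous row
  e <- 0.01
  expect_equal(unname(K["1", ]), c(e * (1 - e), (1 - e)^2 + e^2, e * (1 - e)))
})

test_that("simulated concordance matches the enumeration oracle within 3 SE", {
  cfg <- phr_only(n_samples = 150, n_snps = 1500, seed = 27,
                  error_rate_left = 0.01, error_rate_right = 0.02,
                  missing_rate_left = 0.01, missing_rate_right = 0.01)
  sim <- simulate_dual_platform(cfg)
  exp <- expected_pair_stats(0.01, 0.02, sim$truth$freq_b)
  ov <- summarize_concordance(sim$pair, "overall")
  se <- sqrt(exp$genotype_concordance * (1 - exp$genotype_concordance) /
               ov$n_compared)
  expect_lt(abs(ov$genotype_concordance - exp$genotype_concordance), 3 * se)
  # allele concordance is a mean of per-cell |d|/2 with d in {0,1,2}; bound
  # its sampling error by 3 * sqrt(E[d^2]/n)/2 with E[d^2] <= 2 * (1 - AC)
  d2 <- 2 * (1 - exp$allele_concordance)
  expect_lt(abs(ov$allele_concordance - exp$allele_concordance),
            3 * sqrt(d2 / ov$n_compared) / 2)
})

test_that("category labels respect their constraints and target shares", {
  cfg <- simulation_config(n_samples = 4, n_snps = 5000,
                           monomorphic_fraction = 0.05, seed = 44)
  sim <- simulate_dual_platform(cfg)
  lab <- sim$pair$right$snps$category
  expect_false(anyNA(lab))
  expect_true(all(sim$truth$maf[lab == "MonoHighResolution"] == 0))
  expect_true(all(is.na(sim$pair$left$snps$category)))
  for (nm in names(cfg$category_fractions)) {
    p <- cfg$category_fractions[[nm]]
    obs <- mean(lab == nm)
    tol <- 3 * sqrt(p * (1 - p) / 5000) + 1e-9
    expect_lt(abs(obs - p), max(tol, 0.01))
  }
  # poorly clustering categories really are less concordant
  per_snp <- summarize_concordance(sim$pair, "snp")
  cs <- category_summary(sim$pair, per_snp)$table
  g <- function(nm) cs$genotype_concordance_mean[cs$bin_label == nm]
  expect_lt(g("OffTargetVariant"), g("PolyHighResolution"))
  expect_lt(g("Other"), g("PolyHighResolution"))
  # CallRateBelowThres SNPs carry the elevated missingness
  cr <- snp_call_rates(sim$pair$right)
  expect_lt(mean(cr[lab == "CallRateBelowThres"]),
            mean(cr[lab == "PolyHighResolution"]))
})

test_that("coupled quality recovers the configured concordant/discordant gap", {
  cfg <- phr_only(n_samples = 100, n_snps = 1000, seed = 55,
                  error_rate_left = 0.02, error_rate_right = 0.02)
  pair <- simulate_dual_platform(cfg)$pair
  qc <- quality_mean_comparison(pair, "left")
  expect_lt(qc$mean_quality_discordant, qc$mean_quality_concordant)
  # conditioning on the true error indicator recovers the configured gap
  gap_cfg <- with(cfg, quality_concordant_law$shape1 /
                    (quality_concordant_law$shape1 + quality_concordant_law$shape2) -
                  quality_discordant_law$shape1 /
                    (quality_discordant_law$shape1 + quality_discordant_law$shape2))
  err <- attr(pair$left, "error")
  q_err <- pair$left$quality[which(err)]
  q_ok <- pair$left$quality[which(!err)]
  gap_obs <- mean(q_ok) - mean(q_err)
  se <- sqrt(stats::var(q_ok) / length(q_ok) + stats::var(q_err) / length(q_err))
  expect_lt(abs(gap_obs - gap_cfg), 3 * se)

  ind <- phr_only(n_samples = 50, n_snps = 500, seed = 56,
                  error_rate_left = 0.02, error_rate_right = 0.02,
                  quality_error_coupling = "independent")
  qc_ind <- quality_mean_comparison(simulate_dual_platform(ind)$pair, "left")
  expect_gt(qc_ind$p_value, 1e-6)
})

test_that("the genotype-level error mode makes opposite homozygotes common", {
  cfg_a <- phr_only(n_samples = 100, n_snps = 500, seed = 61,
                    error_rate_left = 0.05, error_rate_right = 0.05)
  cfg_g <- phr_only(n_samples = 100, n_snps = 500, seed = 61,
                    error_rate_left = 0.05, error_rate_right = 0.05,
                    error_model = "genotype")
  ct_a <- contingency_table(simulate_dual_platform(cfg_a)$pair)
  ct_g <- contingency_table(simulate_dual_platform(cfg_g)$pair)
  expect_gt(ct_g$opposite_hom_prop_left, ct_a$opposite_hom_prop_left)
})

test_that("exact-count fixtures embody their specifications", {
  fx <- make_sample_filter_fixture(n_samples = 30, n_fail_left = 3,
                                   n_fail_right = 2, n_fail_both = 1,
                                   n_snps = 40)
  res <- filter_samples_by_call_rate(fx$left, fx$right, 0.9)
  expect_equal(res$audit$n_samples_retained, fx$n_retained)
  expect_equal(fx$n_retained, 26L)

  ov <- make_snp_overlap_fixture(n_left = 100, n_absent_right = 10, n_drop = 5)
  m <- match_snps(ov$left, ov$right, ov$drop_ids)
  expect_equal(m$audit$n_snps_common, 85L)

  df <- make_callset_diff_fixture(n_cells = 1000, n_diff = 10, n_opposite_hom = 2)
  cc <- compare_callsets(df$a, df$b)
  expect_equal(cc$n_different, 10L)
  expect_equal(cc$n_opposite_hom, 2L)

  cr <- make_snp_callrate_fixture(n_snps = 500, n_low = 7, n_samples = 20)
  expect_equal(sum(snp_call_rates(cr) < 0.9), 7L)

  expect_error(make_callset_diff_fixture(10, 20), class = "config_error")
  expect_error(make_sample_filter_fixture(n_samples = 3, n_fail_left = 2,
                                          n_fail_right = 2, n_fail_both = 0),
               class = "config_error")
})
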