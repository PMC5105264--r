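test_that("call rates are simple non-missing fractions", {
  ds <- random_platform_dataset(n = 4, m = 100, missing = 0, quality = FALSE)
  expect_equal(sample_call_rate(ds, ds$sample_ids[1]), 1.0)
  ds$calls[2, 1:3] <- NA_integer_
  expect_equal(sample_call_rate(ds, ds$sample_ids[2]), 0.97)
  ds$calls[3, ] <- NA_integer_
  expect_equal(sample_call_rate(ds, ds$sample_ids[3]), 0.0)
  expect_error(sample_call_rate(ds, "nobody"), class = "lookup_error")

  ds2 <- random_platform_dataset(n = 84, m = 5, missing = 0, quality = FALSE)
  expect_equal(snp_call_rate(ds2, ds2$snps$snp_id[1]), 1.0)
  ds2$calls[1:9, 2] <- NA_integer_
  expect_equal(snp_call_rate(ds2, ds2$snps$snp_id[2]), 75 / 84)
  expect_true(snp_call_rate(ds2, ds2$snps$snp_id[2]) < 0.90)
  expect_error(snp_call_rate(ds2, "rs9999"), class = "lookup_error")
})

test_that("samples failing on either platform are removed from both", {
  fx <- make_sample_filter_fixture(n_samples = 89, n_fail_left = 2,
                                   n_fail_right = 4, n_fail_both = 1)
  res <- filter_samples_by_call_rate(fx$left, fx$right, 0.9)
  expect_equal(res$audit$n_samples_retained, 84L)
  expect_length(res$audit$samples_failing_left, 2L)
  expect_length(res$audit$samples_failing_right, 4L)
  expect_length(union(res$audit$samples_failing_left,
                      res$audit$samples_failing_right), 5L)
  expect_identical(res$left$sample_ids, res$right$sample_ids)
  expect_length(res$left$sample_ids, 84L)

  expect_error(filter_samples_by_call_rate(fx$left, fx$right, 0),
               class = "config_error")
  expect_error(filter_samples_by_call_rate(fx$left, fx$right, 1.5),
               class = "config_error")
})

test_that("nothing changes when every sample passes", {
  l <- random_platform_dataset(n = 5, m = 30, missing = 0, quality = FALSE)
  r <- random_platform_dataset(n = 5, m = 30, missing = 0, quality = FALSE)
  r$sample_ids <- l$sample_ids
  dimnames(r$calls)[[1]] <- l$sample_ids
  res <- filter_samples_by_call_rate(l, r, 0.9)
  expect_identical(res$left$calls, l$calls)
  expect_length(res$audit$samples_failing_left, 0L)
  expect_equal(res$audit$n_samples_retained, 5L)
})

test_that("audit arithmetic matches brute-force set union on random failures", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    nl <- sample(0:4, 1); nr <- sample(0:4, 1)
    nb <- if (min(nl, nr) > 0) sample(0:min(nl, nr), 1) else 0L
    fx <- make_sample_filter_fixture(n_samples = n, n_fail_left = nl,
                                     n_fail_right = nr, n_fail_both = nb,
                                     n_snps = 50)
    res <- filter_samples_by_call_rate(fx$left, fx$right, 0.9)
    a <- res$audit
    union_bf <- unique(c(a$samples_failing_left, a$samples_failing_right))
    expect_equal(a$n_samples_retained, a$n_samples_initial - length(union_bf))
    expect_equal(a$n_samples_retained, fx$n_retained)
  }
})

test_that("SNP matching keeps the intersection minus explicit drops, in left order", {
  fx <- make_snp_overlap_fixture(n_left = 60, n_absent_right = 7, n_drop = 5)
  m <- match_snps(fx$left, fx$right, fx$drop_ids)
  expect_equal(m$audit$n_snps_common, fx$n_common_expected)
  expect_identical(m$left$snps$snp_id, m$right$snps$snp_id)

  m2 <- match_snps(fx$left, fx$left)
  expect_identical(m2$left$snps$snp_id, fx$left$snps$snp_id)

  other <- random_platform_dataset(n = 2, m = 5, quality = FALSE)
  expect_error(match_snps(fx$left, other), class = "pipeline_error")
})

swap_coding <- function(ds, j, complement = FALSE, swap = FALSE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  a <- ds$snps$allele_a[j]; b <- ds$snps$allele_b[j]
  if (complement) { a <- comp[[a]]; b <- comp[[b]] }
  if (swap) {
    tmp <- a; a <- b; b <- tmp
    ds$calls[, j] <- 2L - ds$calls[, j]
  }
  ds$snps$allele_a[j] <- a; ds$snps$allele_b[j] <- b
  ds
}

test_that("allele-coding reconciliation undoes swaps and strand flips", {
  set.seed(5)
  base <- random_platform_dataset(n = 20, m = 9, missing = 0.05, quality = FALSE)
  right <- base
  right <- swap_coding(right, 2, swap = TRUE)                      # A/B swap
  right <- swap_coding(right, 3, complement = TRUE)                # strand
  right <- swap_coding(right, 4, complement = TRUE, swap = TRUE)   # both
  rec <- reconcile_allele_coding(base, right)
  expect_equal(rec$n_dropped, 0L)
  expect_identical(rec$right$calls, base$calls)
  expect_identical(rec$right$snps$allele_b, base$snps$allele_b)
})

at_snp_pair <- function(left_counts, right_counts, right_swapped = FALSE) {
  n <- length(left_counts)
  snps_l <- snp_records("at1", "1", 1L, "A", "T")
  snps_r <- if (right_swapped) snp_records("at1", "1", 1L, "T", "A") else snps_l
  list(left = platform_dataset("L", sprintf("s%02d", 1:n), snps_l,
                               matrix(as.integer(left_counts), n, 1)),
       right = platform_dataset("R", sprintf("s%02d", 1:n), snps_r,
                                matrix(as.integer(right_counts), n, 1)))
}

test_that("strand-ambiguous SNPs are frequency-rescued only below MAF 0.4", {
  # left B-allele frequency 0.45: ambiguous and not rescuable -> dropped
  counts45 <- c(rep(2L, 9), rep(0L, 11))          # f = 18/40 = 0.45
  p <- at_snp_pair(counts45, counts45)
  rec <- reconcile_allele_coding(p$left, p$right)
  expect_equal(rec$n_dropped, 1L)
  expect_identical(rec$dropped_ids, "at1")

  # left MAF 0.1, right reported with A/B swapped: flip is recovered
  counts10 <- c(rep(2L, 2), rep(0L, 18))          # f = 0.1
  p2 <- at_snp_pair(counts10, 2L - counts10, right_swapped = TRUE)
  rec2 <- reconcile_allele_coding(p2$left, p2$right)
  expect_equal(rec2$n_dropped, 0L)
  expect_identical(rec2$right$calls, p2$left$calls)

  # incompatible letters under all four transformations -> dropped
  bad_r <- p2$right
  bad_r$snps$allele_a <- "C"; bad_r$snps$allele_b <- "G"
  rec3 <- reconcile_allele_coding(p2$left, bad_r)
  expect_equal(rec3$n_dropped, 1L)
})

test_that("error-free pairs are perfectly concordant after reconciliation", {
  cfg <- simulation_config(n_samples = 25, n_snps = 300,
                           error_rate_left = 0, error_rate_right = 0,
                           missing_rate_left = 0, missing_rate_right = 0,
                           callrate_missing_rate = 0,
                           error_boost = c(Other = 0), seed = 9)
  sim <- simulate_dual_platform(cfg)
  right <- sim$pair$right
  set.seed(10)
  scramble <- sample(c("none", "swap", "comp", "both"), 300, replace = TRUE)
  for (j in which(scramble == "swap")) right <- swap_coding(right, j, swap = TRUE)
  for (j in which(scramble == "comp")) right <- swap_coding(right, j, complement = TRUE)
  for (j in which(scramble == "both")) right <- swap_coding(right, j, complement = TRUE, swap = TRUE)
  rec <- reconcile_allele_coding(sim$pair$left, right)
  pair <- aligned_pair(rec$left, rec$right)
  ov <- summarize_concordance(pair, "overall")
  expect_identical(ov$genotype_concordance, 1)
  # only strand-ambiguous SNPs with high left MAF may have been dropped
  maf <- snp_mafs(sim$pair$left)
  amb <- with(sim$pair$left$snps,
              paste0(allele_a, allele_b) %in% c("AT", "TA", "CG", "GC"))
  expect_true(all(rec$dropped_ids %in% sim$pair$left$snps$snp_id[amb & maf >= 0.4]))
})

test_that("matching then filtering commutes with the reverse on shared manifests", {
  set.seed(77)
  l <- random_platform_dataset(n = 12, m = 40, missing = 0.08, quality = FALSE,
                               platform = "L")
  r <- random_platform_dataset(n = 12, m = 40, missing = 0.08, quality = FALSE,
                               platform = "R")
  r$sample_ids <- l$sample_ids; dimnames(r$calls)[[1]] <- l$sample_ids
  r$snps <- l$snps; dimnames(r$calls)[[2]] <- l$snps$snp_id

  m_then_f <- {
    m <- match_snps(l, r)
    filter_samples_by_call_rate(m$left, m$right, 0.9)
  }
  f_then_m <- {
    f <- filter_samples_by_call_rate(l, r, 0.9)
    match_snps(f$left, f$right)
  }
  expect_identical(m_then_f$left$calls, f_then_m$left$calls)
  expect_identical(m_then_f$right$calls, f_then_m$right$calls)
})

test_that("harmonize_pair combines the stage audits coherently", {
  fx <- make_snp_overlap_fixture(n_left = 80, n_absent_right = 10, n_drop = 6,
                                 n_samples = 20)
  pair <- harmonize_pair(fx$left, fx$right, fx$drop_ids, 0.9)
  a <- pair$audit
  expect_equal(a$n_snps_initial_left, 80L)
  expect_equal(a$n_snps_common, 64L)
  expect_equal(a$n_samples_retained, 20L)
  expect_identical(pair$left$snps$snp_id, pair$right$snps$snp_id)
})
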