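# Deterministic exact-count fixture builders. Each constructs the smallest
# dataset embodying a requested accounting property (sample failures, SNP
# overlap, differing cells, sub-threshold call rates, category counts) so
# filter and comparison arithmetic can be checked against known answers.

# minimal missing-call count that pushes a call rate strictly below the
# threshold over n assays
n_missing_to_fail <- function(n, threshold) {
  m <- floor(n * (1 - threshold) + 1e-9) + 1L
  while (m <= n && (n - m) / n >= threshold) m <- m + 1L
  if (m > n) stop_config("cannot fail a %.2f call-rate threshold with %d assays",
                         threshold, n)
  m
}

blank_dataset <- function(platform_name, n_samples, n_snps,
                          sample_prefix = "s", snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%06d", seq_len(n_snps))
  snps <- snp_records(snp_id = snp_ids, chrom = "1", pos = seq_len(n_snps),
                      allele_a = "A", allele_b = "G")
  platform_dataset(platform_name,
                   sprintf("%s%04d", sample_prefix, seq_len(n_samples)),
                   snps,
                   matrix(0L, n_samples, n_snps))
}

#' Fixture: samples failing a call-rate threshold
#'
#' Builds two fully matched datasets in which exactly the requested
#' numbers of samples fall below the call-rate threshold on each platform,
#' with a chosen overlap, so [filter_samples_by_call_rate()] must retain
#' exactly `n_samples - (n_fail_left + n_fail_right - n_fail_both)`
#' samples. All other calls are present and concordant.
#'
#' @param n_samples total shared samples.
#' @param n_fail_left,n_fail_right samples failing on each platform
#'   (each count includes the overlap).
#' @param n_fail_both samples failing on both platforms.
#' @param n_snps SNPs per dataset.
#' @param threshold the call-rate threshold the fixture is built against.
#' @return list with `left`, `right` and the expected `n_retained`.
#' @export
make_sample_filter_fixture <- function(n_samples = 89L, n_fail_left = 2L,
                                       n_fail_right = 4L, n_fail_both = 1L,
                                       n_snps = 200L, threshold = 0.9) {
  if (n_fail_both > min(n_fail_left, n_fail_right)) {
    stop_config("overlap exceeds a per-platform failure count")
  }
  if (n_fail_left + n_fail_right - n_fail_both > n_samples) {
    stop_config("more failing samples than samples")
  }
  left <- blank_dataset("fix_left", n_samples, n_snps)
  right <- blank_dataset("fix_right", n_samples, n_snps)
  m <- n_missing_to_fail(n_snps, threshold)
  fail_right <- seq_len(n_fail_right)
  fail_left <- seq(n_fail_right - n_fail_both + 1L,
                   length.out = n_fail_left)
  left$calls[fail_left, seq_len(m)] <- NA_integer_
  right$calls[fail_right, seq_len(m)] <- NA_integer_
  list(left = left, right = right,
       n_retained = n_samples - length(union(fail_left, fail_right)))
}

#' Fixture: partially overlapping SNP manifests
#'
#' Builds a left dataset with `n_left` SNPs and a right dataset missing
#' the last `n_absent_right` of them, plus a list of `n_drop` further SNP
#' ids to exclude, so [match_snps()] must retain exactly
#' `n_left - n_absent_right - n_drop` SNPs.
#'
#' @param n_left SNPs on the left manifest.
#' @param n_absent_right SNPs absent from the right manifest.
#' @param n_drop additional common SNP ids returned as `drop_ids`.
#' @param n_samples samples per dataset.
#' @return list with `left`, `right`, `drop_ids` and `n_common_expected`.
#' @export
make_snp_overlap_fixture <- function(n_left = 51135L, n_absent_right = 4L,
                                     n_drop = 10L, n_samples = 2L) {
  if (n_absent_right + n_drop >= n_left) stop_config("nothing would remain in common")
  ids <- sprintf("snp%06d", seq_len(n_left))
  right_ids <- ids[seq_len(n_left - n_absent_right)]
  drop_ids <- right_ids[seq_len(n_drop)]
  list(left = blank_dataset("fix_left", n_samples, n_left, snp_ids = ids),
       right = blank_dataset("fix_right", n_samples, length(right_ids),
                             snp_ids = right_ids),
       drop_ids = drop_ids,
       n_common_expected = n_left - n_absent_right - n_drop)
}

#' Fixture: paired call vectors differing at exact positions
#'
#' Two complete allele-count vectors of length `n_cells` differing at
#' exactly `n_diff` positions, of which `n_opposite_hom` are
#' opposite-homozygote (two-allele) differences and the rest one-allele
#' differences, for [compare_callsets()].
#'
#' @param n_cells total calls.
#' @param n_diff differing calls.
#' @param n_opposite_hom differing calls that are opposite homozygotes.
#' @return list with integer vectors `a` and `b`.
#' @export
make_callset_diff_fixture <- function(n_cells = 4263331L, n_diff = 3789L,
                                      n_opposite_hom = 0L) {
  if (n_diff > n_cells || n_opposite_hom > n_diff) {
    stop_config("infeasible difference counts")
  }
  a <- rep(0L, n_cells)
  b <- a
  if (n_diff > 0L) {
    b[seq_len(n_diff)] <- 1L
    if (n_opposite_hom > 0L) b[seq_len(n_opposite_hom)] <- 2L
  }
  list(a = a, b = b)
}

#' Fixture: SNPs below a call-rate threshold
#'
#' A dataset in which exactly `n_low` SNPs have a call rate strictly below
#' `threshold` and all others are fully called, so the flagged fraction
#' from [snp_call_rates()] is exactly `n_low / n_snps`.
#'
#' @param n_snps total SNPs.
#' @param n_low SNPs pushed below the threshold.
#' @param n_samples samples.
#' @param threshold call-rate threshold.
#' @return a [platform_dataset()].
#' @export
make_snp_callrate_fixture <- function(n_snps = 51121L, n_low = 771L,
                                      n_samples = 84L, threshold = 0.9) {
  if (n_low > n_snps) stop_config("n_low exceeds n_snps")
  ds <- blank_dataset("fix", n_samples, n_snps)
  if (n_low > 0L) {
    m <- n_missing_to_fail(n_samples, threshold)
    ds$calls[seq_len(m), seq_len(n_low)] <- NA_integer_
  }
  ds
}

#' Fixture: aligned pair with exact SNP category counts
#'
#' A fully concordant aligned pair whose right-platform SNP records carry
#' category labels with exactly the requested counts; SNPs beyond the
#' labelled ones (up to `n_snps`) stay unlabelled. Used to check category
#' shares against known totals.
#'
#' @param category_counts named integer vector over (a subset of)
#'   [snp_categories()].
#' @param n_snps total SNPs; defaults to `sum(category_counts)`.
#' @param n_samples samples.
#' @return an [aligned_pair()].
#' @export
make_category_fixture <- function(category_counts,
                                  n_snps = sum(category_counts),
                                  n_samples = 2L) {
  if (!all(names(category_counts) %in% snp_categories())) {
    stop_config("unknown category name in category_counts")
  }
  if (sum(category_counts) > n_snps) stop_config("category counts exceed n_snps")
  left <- blank_dataset("fix_left", n_samples, n_snps)
  right <- blank_dataset("fix_right", n_samples, n_snps)
  lab <- rep(NA_character_, n_snps)
  lab[seq_len(sum(category_counts))] <-
    rep(names(category_counts), times = category_counts)
  right$snps$category <- lab
  aligned_pair(left, right)
}
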