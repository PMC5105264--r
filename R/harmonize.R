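#' Filter and matching audit
#'
#' Accounting record produced while two call sets are matched: initial and
#' common SNP counts, SNPs dropped because their allele coding could not be
#' reconciled, and per-platform lists of samples failing the call-rate
#' threshold. The identity
#' `n_samples_retained = n_samples_initial - |union(failing lists)|`
#' always holds.
#'
#' @param n_snps_initial_left,n_snps_initial_right,n_snps_common,
#'   n_snps_dropped_unresolvable,n_samples_initial,n_samples_retained
#'   integer counts.
#' @param samples_failing_left,samples_failing_right character vectors of
#'   sample ids below the call-rate threshold on each platform.
#' @param call_rate_threshold the threshold applied, in (0, 1].
#' @return object of class `filter_audit`.
#' @export
filter_audit <- function(n_snps_initial_left = NA_integer_,
                         n_snps_initial_right = NA_integer_,
                         n_snps_common = NA_integer_,
                         n_snps_dropped_unresolvable = 0L,
                         n_samples_initial = NA_integer_,
                         samples_failing_left = character(),
                         samples_failing_right = character(),
                         n_samples_retained = NA_integer_,
                         call_rate_threshold = NA_real_) {
  structure(list(
    n_snps_initial_left = as.integer(n_snps_initial_left),
    n_snps_initial_right = as.integer(n_snps_initial_right),
    n_snps_common = as.integer(n_snps_common),
    n_snps_dropped_unresolvable = as.integer(n_snps_dropped_unresolvable),
    n_samples_initial = as.integer(n_samples_initial),
    samples_failing_left = as.character(samples_failing_left),
    samples_failing_right = as.character(samples_failing_right),
    n_samples_retained = as.integer(n_samples_retained),
    call_rate_threshold = as.numeric(call_rate_threshold)
  ), class = "filter_audit")
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Filter audit\n")
  cat(sprintf("  SNPs: %s (left) / %s (right) initial, %s common, %s dropped unresolvable\n",
              x$n_snps_initial_left, x$n_snps_initial_right,
              x$n_snps_common, x$n_snps_dropped_unresolvable))
  cat(sprintf("  Samples: %s initial, %s retained (call rate >= %s)\n",
              x$n_samples_initial, x$n_samples_retained, x$call_rate_threshold))
  cat(sprintf("  Failing left: %d, failing right: %d, union: %d\n",
              length(x$samples_failing_left), length(x$samples_failing_right),
              length(union(x$samples_failing_left, x$samples_failing_right))))
  invisible(x)
}

#' Per-sample and per-SNP call rates
#'
#' The call rate of a sample is the fraction of SNPs with a non-missing
#' call; the call rate of a SNP is the fraction of samples with a
#' non-missing call.
#'
#' @param ds a [platform_dataset()].
#' @param sample_id,snp_id a single identifier present in `ds`.
#' @return a number in \[0, 1\]; the vectorised forms return a named vector
#'   over all samples or SNPs.
#' @export
sample_call_rate <- function(ds, sample_id) {
  i <- match(sample_id, ds$sample_ids)
  if (is.na(i)) stop_lookup("unknown sample '%s'", sample_id)
  sum(!is.na(ds$calls[i, ])) / ncol(ds$calls)
}

#' @rdname sample_call_rate
#' @export
sample_call_rates <- function(ds) {
  stats::setNames(rowSums(!is.na(ds$calls)) / ncol(ds$calls), ds$sample_ids)
}

#' @rdname sample_call_rate
#' @export
snp_call_rate <- function(ds, snp_id) {
  j <- match(snp_id, ds$snps$snp_id)
  if (is.na(j)) stop_lookup("unknown snp '%s'", snp_id)
  sum(!is.na(ds$calls[, j])) / nrow(ds$calls)
}

#' @rdname sample_call_rate
#' @export
snp_call_rates <- function(ds) {
  stats::setNames(colSums(!is.na(ds$calls)) / nrow(ds$calls), ds$snps$snp_id)
}

#' Remove samples failing a call-rate threshold on either platform
#'
#' Restricts both datasets to their shared samples, then removes every
#' sample whose call rate is below `threshold` on either platform from
#' both datasets: duplicate genotypes from a failed assay are unreliable on
#' the platform where they failed and uninformative for comparison on the
#' other. The audit records the per-platform failing lists and the union.
#'
#' @param left,right [platform_dataset()]s sharing samples (normally after
#'   [match_snps()], so rates are computed on the common SNP set).
#' @param threshold call-rate threshold in (0, 1]; default 0.90.
#' @return list with elements `left`, `right` and `audit`.
#' @export
filter_samples_by_call_rate <- function(left, right, threshold = 0.9) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop_config("call-rate threshold must be in (0, 1], got %s", threshold)
  }
  shared <- intersect(left$sample_ids, right$sample_ids)
  if (!length(shared)) stop_pipeline("no shared samples between datasets")
  left <- subset_dataset(left, sample_ids = shared)
  right <- subset_dataset(right, sample_ids = shared)

  cr_l <- sample_call_rates(left)
  cr_r <- sample_call_rates(right)
  fail_l <- shared[cr_l < threshold]
  fail_r <- shared[cr_r < threshold]
  keep <- setdiff(shared, union(fail_l, fail_r))
  if (!length(keep)) stop_pipeline("all samples fail the %.2f call-rate threshold", threshold)

  audit <- filter_audit(
    n_samples_initial = length(shared),
    samples_failing_left = fail_l,
    samples_failing_right = fail_r,
    n_samples_retained = length(keep),
    call_rate_threshold = threshold
  )
  list(left = subset_dataset(left, sample_ids = keep),
       right = subset_dataset(right, sample_ids = keep),
       audit = audit)
}

#' Restrict two datasets to their common SNPs
#'
#' Intersects the SNP manifests of two datasets (by `snp_id`), removes any
#' explicitly excluded SNPs, and returns both datasets restricted to the
#' intersection in identical (left-manifest) order. `drop_ids` lets known
#' exclusions — e.g. SNPs one laboratory never returned calls for — be
#' applied without modelling why they were absent.
#'
#' @param left,right [platform_dataset()]s.
#' @param drop_ids SNP ids to exclude from the intersection.
#' @return list with elements `left`, `right` and `audit`.
#' @export
match_snps <- function(left, right, drop_ids = character()) {
  common <- setdiff(intersect(left$snps$snp_id, right$snps$snp_id),
                    drop_ids)
  if (!length(common)) stop_pipeline("no common SNPs between datasets")
  common <- left$snps$snp_id[left$snps$snp_id %in% common]
  audit <- filter_audit(
    n_snps_initial_left = nrow(left$snps),
    n_snps_initial_right = nrow(right$snps),
    n_snps_common = length(common)
  )
  list(left = subset_dataset(left, snp_ids = common),
       right = subset_dataset(right, snp_ids = common),
       audit = audit)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reconcile A/B allele coding between matched call sets
#'
#' Different vendors may label the same physical SNP on opposite strands or
#' with A/B swapped, so equal allele counts need not mean equal genotypes.
#' For every SNP the right dataset's coding is tested, in order, as
#' identity, A/B swap (counts c become 2 - c), strand complement, and
#' complement plus swap, and transformed so its `allele_b` is the same
#' physical allele as the left dataset's.
#'
#' For strand-ambiguous SNPs (A/T or C/G) the letters cannot distinguish a
#' swap from a complement. When the left minor allele frequency is below
#' 0.4 the orientation whose B-allele frequency lies closer to the left
#' dataset's is chosen; otherwise the SNP is dropped from both datasets as
#' unresolvable, as are SNPs whose letters are incompatible under all four
#' transformations. SNPs without allele letters (plain call tables) are
#' assumed to share the left coding already.
#'
#' @param left,right [platform_dataset()]s already restricted to common
#'   SNPs in identical order (see [match_snps()]).
#' @param maf_rescue_limit strand-ambiguous SNPs are frequency-matched only
#'   when the left MAF is below this; default 0.4.
#' @return list with elements `left`, `right` (both minus dropped SNPs),
#'   `n_dropped` and `dropped_ids`.
#' @export
reconcile_allele_coding <- function(left, right, maf_rescue_limit = 0.4) {
  if (!identical(left$snps$snp_id, right$snps$snp_id)) {
    stop_data("reconcile_allele_coding requires matched SNPs in identical order")
  }
  n <- nrow(left$snps)
  la <- left$snps$allele_a;  lb <- left$snps$allele_b
  ra <- right$snps$allele_a; rb <- right$snps$allele_b
  has_letters <- !is.na(la) & !is.na(lb) & !is.na(ra) & !is.na(rb)

  keep_ok <- (ra == la & rb == lb) |
    (COMPLEMENT[ra] == la & COMPLEMENT[rb] == lb)
  flip_ok <- (ra == lb & rb == la) |
    (COMPLEMENT[ra] == lb & COMPLEMENT[rb] == la)
  keep_ok[!has_letters] <- TRUE   # letterless SNPs: trust shared coding
  flip_ok[!has_letters] <- FALSE

  flip <- rep(FALSE, n)
  drop <- rep(FALSE, n)
  ambiguous <- which(keep_ok & flip_ok)
  if (length(ambiguous)) {
    f_l <- colMeans(left$calls[, ambiguous, drop = FALSE], na.rm = TRUE) / 2
    f_r <- colMeans(right$calls[, ambiguous, drop = FALSE], na.rm = TRUE) / 2
    maf_l <- pmin(f_l, 1 - f_l)
    rescuable <- !is.na(maf_l) & maf_l < maf_rescue_limit & !is.na(f_r)
    drop[ambiguous[!rescuable]] <- TRUE
    resc <- ambiguous[rescuable]
    flip[resc] <- abs((1 - f_r[rescuable]) - f_l[rescuable]) <
      abs(f_r[rescuable] - f_l[rescuable])
  }
  drop[!keep_ok & !flip_ok] <- TRUE
  flip[!keep_ok & flip_ok] <- TRUE

  if (any(flip)) {
    right$calls[, flip] <- 2L - right$calls[, flip]
  }
  # after transformation the right coding is the left coding
  right$snps$allele_a[has_letters] <- la[has_letters]
  right$snps$allele_b[has_letters] <- lb[has_letters]

  dropped_ids <- left$snps$snp_id[drop]
  if (any(drop)) {
    keep_ids <- left$snps$snp_id[!drop]
    if (!length(keep_ids)) {
      warning("every SNP was unresolvable during allele reconciliation")
    }
    left <- subset_dataset(left, snp_ids = keep_ids)
    right <- subset_dataset(right, snp_ids = keep_ids)
  }
  list(left = left, right = right,
       n_dropped = length(dropped_ids), dropped_ids = dropped_ids)
}

#' Match, reconcile and filter two call sets end to end
#'
#' Runs the full harmonization sequence: SNP intersection (minus
#' `drop_ids`), allele-coding reconciliation, then sample call-rate
#' filtering computed on the matched SNP set, returning an
#' [aligned_pair()] whose audit combines all three stages. SNP matching is
#' done first so that per-sample call rates are comparable across
#' platforms.
#'
#' @param left,right [platform_dataset()]s over overlapping samples/SNPs.
#' @param drop_ids SNP ids excluded up front (see [match_snps()]).
#' @param call_rate_threshold sample call-rate threshold; default 0.90.
#' @param maf_rescue_limit see [reconcile_allele_coding()].
#' @return an [aligned_pair()].
#' @export
harmonize_pair <- function(left, right, drop_ids = character(),
                           call_rate_threshold = 0.9,
                           maf_rescue_limit = 0.4) {
  m <- match_snps(left, right, drop_ids)
  r <- reconcile_allele_coding(m$left, m$right, maf_rescue_limit)
  f <- filter_samples_by_call_rate(r$left, r$right, call_rate_threshold)
  audit <- filter_audit(
    n_snps_initial_left = m$audit$n_snps_initial_left,
    n_snps_initial_right = m$audit$n_snps_initial_right,
    n_snps_common = m$audit$n_snps_common - r$n_dropped,
    n_snps_dropped_unresolvable = r$n_dropped,
    n_samples_initial = f$audit$n_samples_initial,
    samples_failing_left = f$audit$samples_failing_left,
    samples_failing_right = f$audit$samples_failing_right,
    n_samples_retained = f$audit$n_samples_retained,
    call_rate_threshold = call_rate_threshold
  )
  aligned_pair(f$left, f$right, audit)
}
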