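#' Number of alleles shared by two genotypes
#'
#' For B-allele counts `c1`, `c2` in \{0, 1, 2\}, the size of the
#' intersection of the two allele multisets: identical genotypes share 2
#' alleles, a heterozygous/homozygous disagreement shares 1, opposite
#' homozygotes share 0. Closed form `2 - |c1 - c2|`. Vectorised.
#'
#' @param c1,c2 integer vectors of allele counts; missing values are a
#'   precondition error — callers must pairwise-delete first.
#' @return integer vector in \{0, 1, 2\}.
#' @export
shared_alleles <- function(c1, c2) {
  if (anyNA(c1) || anyNA(c2)) {
    stop_data("shared_alleles requires non-missing calls; pre-filter missing cells")
  }
  if (!all(c1 %in% 0:2) || !all(c2 %in% 0:2)) {
    stop_data("allele counts must be 0, 1 or 2")
  }
  2L - abs(c1 - c2)
}

#' Concordance statistics between two allele-count vectors
#'
#' All three statistics use pairwise deletion: a position contributes only
#' when both vectors are non-missing there.
#' `genotype_concordance()` is the proportion of compared positions with
#' identical calls; `allele_concordance()` is the proportion of compared
#' alleles shared (equivalently `1 - mean(|x - y|) / 2`), so it always
#' satisfies `AC = GC + 0.5 * p1` where `p1` is the proportion of compared
#' positions differing by exactly one allele; `allele_count_correlation()`
#' is the Pearson correlation, `NA` when fewer than two compared positions
#' remain or either restricted vector is constant (e.g. a monomorphic SNP).
#'
#' @param x,y equal-length vectors of allele counts in \{0, 1, 2, NA\}.
#' @return a single number (`NA` with a warning when no position is
#'   pairwise complete).
#' @export
genotype_concordance <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) {
    warning("no pairwise-complete positions; genotype concordance is NA")
    return(NA_real_)
  }
  sum(x[ok] == y[ok]) / sum(ok)
}

#' @rdname genotype_concordance
#' @export
allele_concordance <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) {
    warning("no pairwise-complete positions; allele concordance is NA")
    return(NA_real_)
  }
  sum(shared_alleles(x[ok], y[ok])) / (2 * sum(ok))
}

#' @rdname genotype_concordance
#' @export
allele_count_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) {
    warning("no pairwise-complete positions; correlation is NA")
    return(NA_real_)
  }
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Vectorised per-column concordance statistics for two aligned matrices.
# Returns a data.frame with one row per column; the workhorse behind
# summarize_concordance() so that 50k-SNP datasets need no per-SNP loop.
columnwise_stats <- function(X, Y) {
  ok <- !is.na(X) & !is.na(Y)
  Xo <- ifelse(ok, X, NA)
  Yo <- ifelse(ok, Y, NA)
  n <- colSums(ok)
  eq <- colSums(Xo == Yo, na.rm = TRUE)
  ad <- colSums(abs(Xo - Yo), na.rm = TRUE)
  sx <- colSums(Xo, na.rm = TRUE);  sy <- colSums(Yo, na.rm = TRUE)
  sxx <- colSums(Xo^2, na.rm = TRUE); syy <- colSums(Yo^2, na.rm = TRUE)
  sxy <- colSums(Xo * Yo, na.rm = TRUE)
  vx <- n * sxx - sx^2
  vy <- n * syy - sy^2
  r <- rep(NA_real_, length(n))
  def <- n >= 2 & vx > 1e-9 & vy > 1e-9
  r[def] <- (n[def] * sxy[def] - sx[def] * sy[def]) / sqrt(vx[def] * vy[def])
  data.frame(
    n_compared = as.integer(n),
    correlation = r,
    genotype_concordance = ifelse(n > 0, eq / n, NA_real_),
    allele_concordance = ifelse(n > 0, 1 - ad / (2 * n), NA_real_)
  )
}

#' Per-animal, per-SNP and overall concordance summaries
#'
#' Computes the three reproducibility statistics for each unit of an
#' [aligned_pair()]: per animal (across SNPs), per SNP (across animals) or
#' pooled over every compared cell (`unit = "overall"`). Denominators
#' (`n_compared`) are always reported; correlations are `NA` for constant
#' (e.g. monomorphic) units.
#'
#' @param pair an [aligned_pair()].
#' @param unit `"animal"`, `"snp"` or `"overall"`.
#' @return data.frame with columns `unit`, `unit_id`, `n_compared`,
#'   `correlation`, `genotype_concordance`, `allele_concordance`; one row
#'   per unit (a single row with `unit_id = "ALL"` for `"overall"`).
#' @export
summarize_concordance <- function(pair, unit = c("animal", "snp", "overall")) {
  unit <- match.arg(unit)
  X <- pair$left$calls
  Y <- pair$right$calls
  if (unit == "animal") {
    st <- columnwise_stats(t(X), t(Y))
    ids <- pair$left$sample_ids
  } else if (unit == "snp") {
    st <- columnwise_stats(X, Y)
    ids <- pair$left$snps$snp_id
  } else {
    st <- columnwise_stats(matrix(X, ncol = 1L), matrix(Y, ncol = 1L))
    ids <- "ALL"
  }
  cbind(data.frame(unit = unit, unit_id = ids, stringsAsFactors = FALSE), st)
}

#' Mean/min/max overview of per-unit summaries
#'
#' Condenses a per-animal or per-SNP summary table into the headline
#' mean (minimum, maximum) format. Units with `NA` correlation
#' (monomorphic or too few comparisons) are excluded from the correlation
#' mean and counted in `n_na_correlation`.
#'
#' @param summaries output of [summarize_concordance()].
#' @return data.frame with one row per statistic.
#' @export
concordance_overview <- function(summaries) {
  stat_row <- function(name, v) {
    v_ok <- v[!is.na(v)]
    data.frame(statistic = name,
               mean = mean(v_ok), min = min(v_ok), max = max(v_ok),
               n_units = length(v), n_na = sum(is.na(v)))
  }
  rbind(stat_row("correlation", summaries$correlation),
        stat_row("genotype_concordance", summaries$genotype_concordance),
        stat_row("allele_concordance", summaries$allele_concordance))
}

#' Genotype contingency table between two platforms
#'
#' Cross-tabulates every pairwise-complete (sample, SNP) cell of an aligned
#' pair by left genotype (rows, 0/1/2) against right genotype (columns),
#' with row percentages, and reports the opposite-homozygote proportion —
#' cells called homozygous on one platform and as the other homozygote on
#' the second. Because the denominator convention is ambiguous, the
#' proportion is given conditional on the left platform's homozygotes, on
#' the right's, and on their average.
#'
#' @param pair an [aligned_pair()].
#' @return object of class `contingency_table3`: list with `counts`
#'   (3 x 3 integer), `row_percent` (3 x 3), `n_total`, and
#'   `opposite_hom_prop_left`, `opposite_hom_prop_right`,
#'   `opposite_hom_prop_mean`.
#' @export
contingency_table <- function(pair) {
  x <- as.vector(pair$left$calls)
  y <- as.vector(pair$right$calls)
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop_pipeline("no pairwise-complete cells to tabulate")
  counts <- table(factor(x[ok], levels = 0:2), factor(y[ok], levels = 0:2))
  counts <- matrix(as.integer(counts), 3L, 3L,
                   dimnames = list(left = 0:2, right = 0:2))
  rs <- rowSums(counts)
  row_percent <- 100 * counts / ifelse(rs > 0, rs, NA)
  opp <- counts[1L, 3L] + counts[3L, 1L]
  hom_left <- rs[1L] + rs[3L]
  hom_right <- sum(counts[, 1L]) + sum(counts[, 3L])
  structure(list(
    counts = counts, row_percent = row_percent, n_total = sum(counts),
    opposite_hom_prop_left = if (hom_left > 0) unname(opp / hom_left) else NA_real_,
    opposite_hom_prop_right = if (hom_right > 0) unname(opp / hom_right) else NA_real_,
    opposite_hom_prop_mean = if (hom_left > 0 && hom_right > 0)
      unname(opp / mean(c(hom_left, hom_right))) else NA_real_
  ), class = "contingency_table3")
}

#' @export
print.contingency_table3 <- function(x, ...) {
  cat(sprintf("Genotype contingency table (%d compared cells), row %%:\n",
              x$n_total))
  print(round(x$row_percent, 2))
  cat(sprintf("Opposite-homozygote proportion: %.4g (left hom), %.4g (right hom)\n",
              x$opposite_hom_prop_left, x$opposite_hom_prop_right))
  invisible(x)
}

#' Compare two call sets over the same samples and SNPs
#'
#' Cell-by-cell comparison of two call sets of identical shape — e.g. the
#' same intensities genotyped with the vendor cluster file and after
#' re-clustering. Counts cells called in both, cells with a different
#' genotype, and opposite-homozygote differences.
#'
#' @param a,b [platform_dataset()]s or plain allele-count matrices/vectors
#'   of identical shape.
#' @return list with `n_called_both`, `n_different`, `n_opposite_hom` and
#'   `pct_different` (percentage of compared cells that differ).
#' @export
compare_callsets <- function(a, b) {
  X <- if (inherits(a, "platform_dataset")) a$calls else a
  Y <- if (inherits(b, "platform_dataset")) b$calls else b
  if (!identical(dim(X), dim(Y)) || length(X) != length(Y)) {
    stop_data("call sets have different shapes")
  }
  ok <- !is.na(X) & !is.na(Y)
  n <- sum(ok)
  if (n == 0L) stop_pipeline("no cells called in both sets")
  d <- abs(X[ok] - Y[ok])
  list(n_called_both = n,
       n_different = sum(d > 0L),
       n_opposite_hom = sum(d == 2L),
       pct_different = 100 * sum(d > 0L) / n)
}

#' Drop SNPs with poor allele concordance
#'
#' Restricts an aligned pair to SNPs whose between-platform allele
#' concordance is at least `min_allele_concordance`; SNPs with `NA`
#' concordance (nothing compared) are also removed.
#'
#' @param pair an [aligned_pair()].
#' @param per_snp per-SNP summaries from
#'   `summarize_concordance(pair, "snp")`.
#' @param min_allele_concordance threshold in \[0, 1\]; default 0.80.
#' @return the restricted [aligned_pair()]; the number of SNPs removed is
#'   reported via `message()`.
#' @export
filter_snps_by_concordance <- function(pair, per_snp,
                                       min_allele_concordance = 0.8) {
  if (!identical(per_snp$unit_id, pair$left$snps$snp_id)) {
    stop_data("per-SNP summaries do not match the pair's SNPs")
  }
  keep <- !is.na(per_snp$allele_concordance) &
    per_snp$allele_concordance >= min_allele_concordance
  if (!any(keep)) stop_pipeline("no SNP reaches allele concordance %.2f",
                                min_allele_concordance)
  message(sprintf("filter_snps_by_concordance: removed %d of %d SNPs",
                  sum(!keep), length(keep)))
  ids <- pair$left$snps$snp_id[keep]
  aligned_pair(subset_dataset(pair$left, snp_ids = ids),
               subset_dataset(pair$right, snp_ids = ids),
               pair$audit)
}
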