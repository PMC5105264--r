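# Independent oracles and small random-data builders used across tests.
# These deliberately avoid the package's own closed forms: shared alleles
# are counted by explicit multiset intersection, summaries by plain loops.

oracle_shared_alleles <- function(c1, c2) {
  multiset <- function(c) c(rep("A", 2 - c), rep("B", c))
  mapply(function(a, b) {
    m1 <- multiset(a); m2 <- multiset(b)
    shared <- 0L
    for (al in m1) {
      hit <- match(al, m2)
      if (!is.na(hit)) { shared <- shared + 1L; m2 <- m2[-hit] }
    }
    shared
  }, c1, c2)
}

# plain-loop per-unit statistics, one unit at a time
oracle_unit_stats <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  r <- if (length(x) >= 2 && stats::sd(x) > 0 && stats::sd(y) > 0)
    stats::cor(x, y) else NA_real_
  list(n = length(x), cor = r,
       gc = mean(x == y),
       ac = sum(oracle_shared_alleles(x, y)) / (2 * length(x)))
}

# random dataset built directly, independent of the package simulator
random_platform_dataset <- function(n = 6L, m = 10L, missing = 0.15,
                                    quality = TRUE, platform = "rand",
                                    orientation = "higher_is_better") {
  calls <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                         prob = c((1 - missing) / 3, (1 - missing) / 3,
                                  (1 - missing) / 3, missing)),
                  n, m)
  q <- NULL
  if (quality) {
    q <- matrix(round(stats::runif(n * m), 6), n, m)
    q[is.na(calls)] <- NA
  }
  pairs <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  al <- pairs[sample.int(4L, m, replace = TRUE)]
  snps <- snp_records(
    snp_id = sprintf("rs%04d", seq_len(m)),
    chrom = sample(as.character(1:5), m, replace = TRUE),
    pos = sort(sample.int(10000L, m)),
    allele_a = vapply(al, `[`, "", 1L),
    allele_b = vapply(al, `[`, "", 2L),
    category = sample(c(snp_categories(), NA), m, replace = TRUE)
  )
  platform_dataset(platform, sprintf("ind%03d", seq_len(n)), snps, calls,
                   q, orientation)
}

# a concordant aligned pair with injected per-cell overrides
manual_pair <- function(left_calls, right_calls, left_quality = NULL,
                        right_quality = NULL, categories = NA_character_) {
  n <- nrow(left_calls); m <- ncol(left_calls)
  snps <- snp_records(sprintf("mp%04d", seq_len(m)), chrom = "1",
                      pos = seq_len(m), allele_a = "A", allele_b = "G",
                      category = categories)
  ids <- sprintf("an%03d", seq_len(n))
  aligned_pair(
    platform_dataset("left", ids, snps, left_calls, left_quality),
    platform_dataset("right", ids, snps, right_calls, right_quality)
  )
}
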