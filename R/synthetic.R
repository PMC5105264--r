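#' Configuration for the dual-platform genotype simulator
#'
#' Bundles every simulator parameter. Defaults emulate the cross-platform
#' technical-replicate design this package targets: 84 individuals assayed
#' at 51,121 SNPs on a higher-quality "left" platform (Illumina-like GC
#' scores, higher is better) and a noisier "right" platform
#' (Affymetrix-like confidence scores, lower is better). Error rates are
#' per-allele miscall probabilities, so opposite-homozygote miscalls arise
#' only when both alleles flip (probability on the order of the rate
#' squared). Quality scores are Beta draws whose means differ between
#' correct calls (about 0.89) and erroneous calls (about 0.85) when
#' `quality_error_coupling = "coupled"`. SNP category labels follow
#' `category_fractions`; `CallRateBelowThres` SNPs receive
#' `callrate_missing_rate` missingness and `OffTargetVariant`/`Other` SNPs
#' receive `error_boost` extra per-allele error.
#'
#' @param n_samples,n_snps dataset dimensions.
#' @param maf_law minor-allele-frequency law for polymorphic SNPs: one of
#'   `maf_uniform(lo, hi)`, `maf_beta(a, b)`, `maf_point_mass(value)`.
#' @param monomorphic_fraction fraction of SNPs forced to MAF 0.
#' @param error_rate_left,error_rate_right per-allele miscall probability
#'   in \[0, 0.5).
#' @param missing_rate_left,missing_rate_right per-call no-call probability
#'   in \[0, 1).
#' @param quality_concordant_law,quality_discordant_law `list(shape1,
#'   shape2)` Beta parameters for correct and erroneous calls.
#' @param quality_error_coupling `"coupled"` (erroneous calls draw from the
#'   discordant law) or `"independent"`.
#' @param category_fractions named non-negative weights over the six
#'   [snp_categories()]; must sum to 1.
#' @param error_boost named extra per-allele error for poorly clustering
#'   categories.
#' @param callrate_missing_rate missingness applied to
#'   `CallRateBelowThres` SNPs on both platforms.
#' @param error_model `"allele"` (each allele flips independently) or
#'   `"genotype"` (whole call replaced by another genotype, a stress-test
#'   mode in which opposite homozygotes are not rare).
#' @param quality_orientation_left,quality_orientation_right score
#'   orientation per platform.
#' @param seed integer RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 84L,
                              n_snps = 51121L,
                              maf_law = maf_uniform(0.01, 0.5),
                              monomorphic_fraction = 0.03,
                              error_rate_left = 0.001,
                              error_rate_right = 0.0035,
                              missing_rate_left = 0.006,
                              missing_rate_right = 0.026,
                              quality_concordant_law = list(shape1 = 8.9, shape2 = 1.1),
                              quality_discordant_law = list(shape1 = 8.5, shape2 = 1.5),
                              quality_error_coupling = c("coupled", "independent"),
                              category_fractions = default_category_fractions(),
                              error_boost = c(MonoHighResolution = 0.015,
                                              CallRateBelowThres = 0.011,
                                              OffTargetVariant = 0.074,
                                              Other = 0.047),
                              callrate_missing_rate = 0.15,
                              error_model = c("allele", "genotype"),
                              quality_orientation_left = "higher_is_better",
                              quality_orientation_right = "lower_is_better",
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    maf_law = maf_law,
    monomorphic_fraction = monomorphic_fraction,
    error_rate_left = error_rate_left, error_rate_right = error_rate_right,
    missing_rate_left = missing_rate_left, missing_rate_right = missing_rate_right,
    quality_concordant_law = quality_concordant_law,
    quality_discordant_law = quality_discordant_law,
    quality_error_coupling = match.arg(quality_error_coupling),
    category_fractions = category_fractions,
    error_boost = error_boost,
    callrate_missing_rate = callrate_missing_rate,
    error_model = match.arg(error_model),
    quality_orientation_left = quality_orientation_left,
    quality_orientation_right = quality_orientation_right,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @param lo,hi,a,b,value law parameters.
#' @export
maf_uniform <- function(lo = 0, hi = 0.5) {
  if (lo < 0 || hi > 0.5 || lo > hi) stop_config("uniform MAF law needs 0 <= lo <= hi <= 0.5")
  list(kind = "uniform", lo = lo, hi = hi)
}

#' @rdname simulation_config
#' @export
maf_beta <- function(a, b) {
  if (a <= 0 || b <= 0) stop_config("beta MAF law needs positive shapes")
  list(kind = "beta", a = a, b = b)
}

#' @rdname simulation_config
#' @export
maf_point_mass <- function(value) {
  if (value < 0 || value > 0.5) stop_config("point-mass MAF must lie in [0, 0.5]")
  list(kind = "point_mass", value = value)
}

#' @rdname simulation_config
#' @export
default_category_fractions <- function() {
  # Axiom category mix typical of a mid-density custom array: dominated by
  # PolyHighResolution, a few percent NoMinorHom and monomorphic SNPs, and
  # a tail of poorly clustering probe sets.
  n <- c(PolyHighResolution = 37619, NoMinorHom = 2135,
         MonoHighResolution = 972, OffTargetVariant = 463,
         CallRateBelowThres = 4288, Other = 5641)
  n / sum(n)
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 1L || n_snps < 1L) stop_config("n_samples and n_snps must be positive")
    if (monomorphic_fraction < 0 || monomorphic_fraction >= 1) {
      stop_config("monomorphic_fraction must lie in [0, 1)")
    }
    for (e in c(error_rate_left, error_rate_right)) {
      if (e < 0 || e >= 0.5) stop_config("per-allele error rates must lie in [0, 0.5)")
    }
    for (m in c(missing_rate_left, missing_rate_right)) {
      if (m < 0 || m >= 1) stop_config("missing rates must lie in [0, 1)")
    }
    if (!setequal(names(category_fractions), snp_categories())) {
      stop_config("category_fractions must name exactly the six SNP categories")
    }
    if (any(category_fractions < 0) ||
        abs(sum(category_fractions) - 1) > 1e-8) {
      stop_config("category_fractions must be non-negative and sum to 1")
    }
    if (category_fractions[["MonoHighResolution"]] > monomorphic_fraction + 1e-12) {
      stop_config("MonoHighResolution fraction (%g) exceeds monomorphic_fraction (%g)",
                  category_fractions[["MonoHighResolution"]], monomorphic_fraction)
    }
  })
  invisible(cfg)
}

#' Simulate true genotypes under Hardy-Weinberg equilibrium
#'
#' Draws a per-SNP B-allele frequency from the configured MAF law (with
#' `monomorphic_fraction` of SNPs forced to frequency 0), then genotypes
#' for every sample as Binomial(2, freq) — Hardy-Weinberg proportions with
#' no linkage or pedigree structure. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return object of class `truth_set`: list with `true_calls` (complete
#'   allele-count matrix), `freq_b`, `maf`, `snps` ([snp_records()] with
#'   random allele letters), and `category` (filled by
#'   [simulate_dual_platform()]).
#' @export
simulate_truth <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_samples; m <- cfg$n_snps
  f <- switch(cfg$maf_law$kind,
    uniform = stats::runif(m, cfg$maf_law$lo, cfg$maf_law$hi),
    beta = 0.5 * stats::rbeta(m, cfg$maf_law$a, cfg$maf_law$b),
    point_mass = rep(cfg$maf_law$value, m),
    stop_config("unknown MAF law '%s'", cfg$maf_law$kind)
  )
  n_mono <- round(m * cfg$monomorphic_fraction)
  if (n_mono > 0L) f[sample.int(m, n_mono)] <- 0
  true_calls <- matrix(
    stats::rbinom(n * m, 2L, rep(f, each = n)),
    nrow = n, ncol = m
  )
  storage.mode(true_calls) <- "integer"
  bases <- c("A", "C", "G", "T")
  aa <- sample(bases, m, replace = TRUE)
  bb <- vapply(aa, function(x) sample(setdiff(bases, x), 1L), "")
  snps <- snp_records(
    snp_id = sprintf("snp%06d", seq_len(m)),
    chrom = as.character(1L + (seq_len(m) - 1L) %% 26L),
    pos = seq_len(m),
    allele_a = aa, allele_b = unname(bb)
  )
  structure(list(true_calls = true_calls, freq_b = f, maf = pmin(f, 1 - f),
                 snps = snps, category = rep(NA_character_, m)),
            class = "truth_set")
}

# Per-SNP effective error and missing rates for one platform, given the
# truth's category labels.
platform_rates <- function(truth, side, cfg) {
  m <- cfg$n_snps
  eps <- rep(if (side == "left") cfg$error_rate_left else cfg$error_rate_right, m)
  miss <- rep(if (side == "left") cfg$missing_rate_left else cfg$missing_rate_right, m)
  cat_lab <- truth$category
  for (nm in names(cfg$error_boost)) {
    eps[!is.na(cat_lab) & cat_lab == nm] <-
      pmin(eps[!is.na(cat_lab) & cat_lab == nm] + cfg$error_boost[[nm]], 0.499)
  }
  miss[!is.na(cat_lab) & cat_lab == "CallRateBelowThres"] <-
    pmax(miss[!is.na(cat_lab) & cat_lab == "CallRateBelowThres"],
         cfg$callrate_missing_rate)
  list(eps = eps, miss = miss)
}

#' Apply a platform's error, missingness and quality model to the truth
#'
#' Under the allele error model each of a call's two alleles is
#' independently miscalled with the platform's per-allele rate, so the
#' observed count moves by at most one per flipped allele and opposite
#' homozygotes require two flips. Cells are then masked missing at the
#' platform's no-call rate. Quality scores are Beta draws; with coupled
#' quality, erroneous calls draw from the (lower-mean) discordant law.
#' Scores are stored as `1 - q` for a lower-is-better platform. Uses the
#' current RNG stream; seed via [simulate_truth()] or
#' [simulate_dual_platform()].
#'
#' @param truth a `truth_set` from [simulate_truth()].
#' @param side `"left"` or `"right"`.
#' @param cfg the [simulation_config()] used to build `truth`.
#' @return a [platform_dataset()]; the per-cell error indicator matrix is
#'   attached as attribute `"error"`.
#' @export
apply_platform_error <- function(truth, side = c("left", "right"), cfg) {
  side <- match.arg(side)
  rates <- platform_rates(truth, side, cfg)
  n <- cfg$n_samples; m <- cfg$n_snps
  t_vec <- as.vector(truth$true_calls)
  p <- rep(rates$eps, each = n)
  if (cfg$error_model == "allele") {
    b_to_a <- stats::rbinom(n * m, t_vec, p)
    a_to_b <- stats::rbinom(n * m, 2L - t_vec, p)
    obs <- t_vec - b_to_a + a_to_b
  } else {
    # genotype-level stress-test mode: whole call replaced by one of the
    # other two genotypes with probability 2 * eps
    hit <- stats::rbinom(n * m, 1L, pmin(2 * p, 1)) == 1L
    shift <- sample(1:2, sum(hit), replace = TRUE)
    obs <- t_vec
    obs[hit] <- (obs[hit] + shift) %% 3L
  }
  err <- obs != t_vec
  law_c <- cfg$quality_concordant_law
  law_d <- cfg$quality_discordant_law
  q <- stats::rbeta(n * m, law_c$shape1, law_c$shape2)
  if (cfg$quality_error_coupling == "coupled" && any(err)) {
    q[err] <- stats::rbeta(sum(err), law_d$shape1, law_d$shape2)
  }
  orientation <- if (side == "left") cfg$quality_orientation_left else
    cfg$quality_orientation_right
  if (orientation == "lower_is_better") q <- 1 - q
  missing <- stats::rbinom(n * m, 1L, rep(rates$miss, each = n)) == 1L
  obs[missing] <- NA_integer_
  q[missing] <- NA_real_
  err[missing] <- NA

  calls <- matrix(as.integer(obs), n, m)
  quality <- matrix(q, n, m)
  snps <- truth$snps
  snps$category <- if (side == "right") truth$category else NA_character_
  ds <- platform_dataset(
    platform_name = paste0("sim_", side),
    sample_ids = sprintf("s%04d", seq_len(n)),
    snps = snps, calls = calls, quality = quality,
    quality_orientation = orientation
  )
  attr(ds, "error") <- matrix(err, n, m)
  ds
}

#' Simulate an aligned dual-platform call-set pair with known truth
#'
#' Draws the Hardy-Weinberg truth, attaches Axiom-style category labels
#' (MonoHighResolution only on truth-monomorphic SNPs; poorly clustering
#' categories receive elevated error or missingness per the config), and
#' applies each platform's error model. The two datasets share samples,
#' SNPs and allele coding, so they form an [aligned_pair()] directly.
#'
#' @param cfg a [simulation_config()].
#' @return list with `pair` (an [aligned_pair()]) and `truth` (the
#'   `truth_set`, including `category`).
#' @export
simulate_dual_platform <- function(cfg) {
  validate_simulation_config(cfg)
  truth <- simulate_truth(cfg)   # seeds the stream
  m <- cfg$n_snps
  labels <- sample(names(cfg$category_fractions), m, replace = TRUE,
                   prob = cfg$category_fractions)
  mono_idx <- which(truth$maf == 0)
  is_mono_label <- labels == "MonoHighResolution"
  k <- sum(is_mono_label)
  if (k > length(mono_idx)) {
    # sampling noise overshot the monomorphic pool; excess labels become
    # "Other" so the label-consistency constraint holds
    excess <- which(is_mono_label)[seq_len(k - length(mono_idx))]
    labels[excess] <- "Other"
    is_mono_label <- labels == "MonoHighResolution"
    k <- sum(is_mono_label)
  }
  placed <- rep(NA_character_, m)
  if (k > 0L) {
    placed[sample(mono_idx, k)] <- "MonoHighResolution"
  }
  placed[is.na(placed)] <- sample(labels[!is_mono_label])
  truth$category <- placed

  left <- apply_platform_error(truth, "left", cfg)
  right <- apply_platform_error(truth, "right", cfg)
  list(pair = aligned_pair(left, right, audit = NULL), truth = truth)
}

#' Exact per-allele miscall kernel
#'
#' The 3 x 3 matrix `K[t, o]` of probabilities that a true allele count
#' `t` is observed as `o` when each of the two alleles independently flips
#' with probability `eps`, computed by exact binomial enumeration. Row
#' `t = 0` gives the one-flip probability `2 eps (1 - eps)` and the
#' two-flip (opposite homozygote) probability `eps^2`.
#'
#' @param eps per-allele miscall probability.
#' @return 3 x 3 matrix with rows/columns named 0:2.
#' @export
allele_error_kernel <- function(eps) {
  K <- matrix(0, 3L, 3L, dimnames = list(true = 0:2, obs = 0:2))
  for (t in 0:2) {
    for (o in 0:2) {
      p <- 0
      for (x in 0:t) {                 # B alleles flipped to A
        y <- o - t + x                 # A alleles flipped to B
        if (y >= 0 && y <= 2 - t) {
          p <- p + stats::dbinom(x, t, eps) * stats::dbinom(y, 2 - t, eps)
        }
      }
      K[t + 1L, o + 1L] <- p
    }
  }
  K
}

#' Expected cross-platform concordance under the allele error model
#'
#' Brute-force enumeration of the 3 x 3 x 3 (left observation, right
#' observation, truth) kernel: for each SNP's B-allele frequency, truth
#' genotype probabilities are the Hardy-Weinberg proportions and each
#' platform's observation follows [allele_error_kernel()]. Returns the
#' expected genotype concordance, allele concordance and
#' opposite-homozygote rate among pairwise-complete cells, per SNP and
#' averaged over SNPs. This enumeration is the independent expectation the
#' simulator is validated against.
#'
#' @param eps_left,eps_right per-allele miscall probabilities (scalars or
#'   per-SNP vectors).
#' @param freq_b per-SNP true B-allele frequencies.
#' @return list with scalar `genotype_concordance`, `allele_concordance`,
#'   `opposite_hom_rate` (means over SNPs) and the per-SNP vectors.
#' @export
expected_pair_stats <- function(eps_left, eps_right, freq_b) {
  m <- length(freq_b)
  eps_left <- rep_len(eps_left, m)
  eps_right <- rep_len(eps_right, m)
  g <- cbind((1 - freq_b)^2, 2 * freq_b * (1 - freq_b), freq_b^2)
  conc <- dist <- opp <- numeric(m)
  key <- paste(eps_left, eps_right)
  for (k in unique(key)) {
    i <- which(key == k)
    KL <- allele_error_kernel(eps_left[i[1L]])
    KR <- allele_error_kernel(eps_right[i[1L]])
    Jc <- Jd <- Jo <- numeric(3L)
    for (t in 1:3) {
      P <- outer(KL[t, ], KR[t, ])              # P(o1, o2 | truth t)
      Jc[t] <- sum(diag(P))
      Jd[t] <- sum(P * abs(outer(0:2, 0:2, "-")))
      Jo[t] <- P[1L, 3L] + P[3L, 1L]
    }
    conc[i] <- g[i, , drop = FALSE] %*% Jc
    dist[i] <- g[i, , drop = FALSE] %*% Jd
    opp[i] <- g[i, , drop = FALSE] %*% Jo
  }
  list(genotype_concordance = mean(conc),
       allele_concordance = 1 - mean(dist) / 2,
       opposite_hom_rate = mean(opp),
       per_snp_genotype_concordance = conc,
       per_snp_allele_concordance = 1 - dist / 2,
       per_snp_opposite_hom_rate = opp)
}
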