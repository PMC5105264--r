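#' Minor allele frequency of a SNP
#'
#' `min(f, 1 - f)` where `f` is the B-allele frequency, estimated as
#' `mean(calls) / 2` over non-missing calls. Monomorphic SNPs have MAF 0;
#' a SNP with no called genotype has MAF `NA`.
#'
#' @param ds a [platform_dataset()].
#' @param snp_id a single SNP id present in `ds`.
#' @return a number in \[0, 0.5\]; `snp_mafs()` returns the named vector
#'   over all SNPs.
#' @export
compute_maf <- function(ds, snp_id) {
  j <- match(snp_id, ds$snps$snp_id)
  if (is.na(j)) stop_lookup("unknown snp '%s'", snp_id)
  snp_mafs(ds)[[j]]
}

#' @rdname compute_maf
#' @export
snp_mafs <- function(ds) {
  f <- colMeans(ds$calls, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  stats::setNames(pmin(f, 1 - f), ds$snps$snp_id)
}

# Means of per-SNP statistics within groups defined by a factor; the
# common core of the MAF, quality and category stratifiers.
group_means <- function(per_snp, groups, stratifier) {
  groups <- factor(groups)
  split_idx <- split(seq_len(nrow(per_snp)), groups)
  rows <- lapply(names(split_idx), function(g) {
    i <- split_idx[[g]]
    r <- per_snp$correlation[i]
    data.frame(
      stratifier = stratifier,
      bin_label = g,
      n_snps = length(i),
      n_genotypes = sum(per_snp$n_compared[i]),
      correlation_mean = if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE),
      n_na_correlation = sum(is.na(r)),
      genotype_concordance_mean = mean(per_snp$genotype_concordance[i], na.rm = TRUE),
      allele_concordance_mean = mean(per_snp$allele_concordance[i], na.rm = TRUE),
      allele_concordance_sd = stats::sd(per_snp$allele_concordance[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance stratified by minor allele frequency
#'
#' Bins SNPs by MAF on the chosen reference platform — monomorphic SNPs
#' (MAF exactly 0) form their own bin, the rest fall into right-closed
#' intervals (0, w], (w, 2w], ... up to 0.5 — and reports unweighted means
#' of the per-SNP statistics within each bin.
#'
#' @param pair an [aligned_pair()].
#' @param per_snp per-SNP summaries from
#'   `summarize_concordance(pair, "snp")`.
#' @param reference `"left"` or `"right"`: platform whose calls define MAF.
#' @param bin_width MAF bin width; default 0.05.
#' @return data.frame of per-bin summaries (empty bins omitted).
#' @export
stratify_by_maf <- function(pair, per_snp, reference = c("left", "right"),
                            bin_width = 0.05) {
  reference <- match.arg(reference)
  maf <- snp_mafs(pair[[reference]])
  edges <- seq(0, 0.5 + 1e-9, by = bin_width)
  lab <- cut(maf, breaks = edges, right = TRUE, include.lowest = FALSE,
             dig.lab = 3)
  lab <- as.character(lab)
  lab[!is.na(maf) & maf == 0] <- "monomorphic"
  keep <- !is.na(lab)
  group_means(per_snp[keep, , drop = FALSE], lab[keep], "maf")
}

#' Concordance stratified by mean per-SNP quality score
#'
#' Computes each SNP's mean quality score on the chosen platform (over its
#' non-missing calls), bins SNPs by the supplied edges, and reports per-bin
#' mean allele concordance with its standard deviation and SNP counts.
#' Bins are ordered from worst to best quality, honouring the platform's
#' quality orientation (GC score: higher is better; Affymetrix confidence:
#' lower is better, so bin order is reversed).
#'
#' @param pair an [aligned_pair()].
#' @param per_snp per-SNP summaries for `pair`.
#' @param platform `"left"` or `"right"`; that dataset must carry quality.
#' @param bin_edges increasing break points spanning the scores; default
#'   0.05-wide bins on \[0, 1\].
#' @return data.frame of per-bin summaries, plus a `mean_quality` column.
#' @export
stratify_by_quality <- function(pair, per_snp, platform = c("left", "right"),
                                bin_edges = seq(0, 1, by = 0.05)) {
  platform <- match.arg(platform)
  ds <- pair[[platform]]
  if (is.null(ds$quality)) {
    stop_pipeline("platform '%s' carries no quality scores", ds$platform_name)
  }
  q <- ds$quality
  q[is.na(ds$calls)] <- NA
  mq <- colMeans(q, na.rm = TRUE)
  mq[is.nan(mq)] <- NA_real_
  lab <- cut(mq, breaks = bin_edges, right = TRUE, include.lowest = TRUE,
             dig.lab = 3)
  keep <- !is.na(lab)
  out <- group_means(per_snp[keep, , drop = FALSE], droplevels(lab[keep]),
                     "quality")
  agg <- tapply(mq[keep], droplevels(lab[keep]), mean)
  out$mean_quality <- as.numeric(agg[out$bin_label])
  if (ds$quality_orientation == "lower_is_better") {
    out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Mask poor-quality genotype calls
#'
#' Sets genotype cells whose quality score is on the bad side of
#' `threshold` to missing on the chosen platform (score `<=` threshold
#' when higher is better; score `>=` threshold when lower is better), so
#' that downstream statistics are recomputed on the restriction.
#'
#' @param pair an [aligned_pair()].
#' @param platform `"left"` or `"right"`; that dataset must carry quality.
#' @param threshold quality threshold (e.g. GC score 0.55).
#' @return the restricted [aligned_pair()].
#' @export
restrict_by_quality <- function(pair, platform = c("left", "right"),
                                threshold = 0.55) {
  platform <- match.arg(platform)
  ds <- pair[[platform]]
  if (is.null(ds$quality)) {
    stop_pipeline("platform '%s' carries no quality scores", ds$platform_name)
  }
  bad <- if (ds$quality_orientation == "higher_is_better") {
    !is.na(ds$quality) & ds$quality <= threshold
  } else {
    !is.na(ds$quality) & ds$quality >= threshold
  }
  ds$calls[bad] <- NA_integer_
  pair[[platform]] <- ds
  other <- pair[[setdiff(c("left", "right"), platform)]]
  if (!any(!is.na(ds$calls) & !is.na(other$calls))) {
    stop_pipeline("quality restriction at %.3g leaves no comparable cells", threshold)
  }
  pair
}

#' Concordance by Axiom SNP category
#'
#' Groups SNPs by the cluster-quality category label carried on the right
#' platform's SNP records and reports per-category SNP counts, unweighted
#' means of the per-SNP statistics, each category's share of all SNPs, and
#' the pooled genotype concordance over segregating PolyHighResolution
#' SNPs (the restriction a quality-conscious analysis would apply). SNPs
#' without a label are reported as `Unlabelled`.
#'
#' @param pair an [aligned_pair()].
#' @param per_snp per-SNP summaries for `pair`.
#' @return list with `table` (per-category data.frame including
#'   `share_pct`) and `poly_high_res_pooled_gc`.
#' @export
category_summary <- function(pair, per_snp) {
  cat_lab <- pair$right$snps$category
  cat_lab[is.na(cat_lab)] <- "Unlabelled"
  lev <- c(snp_categories(), "Unlabelled")
  cat_lab <- factor(cat_lab, levels = lev[lev %in% unique(cat_lab)])
  out <- group_means(per_snp, cat_lab, "category")
  out$share_pct <- 100 * out$n_snps / sum(out$n_snps)

  maf_l <- snp_mafs(pair$left)
  seg_phr <- which(cat_lab == "PolyHighResolution" &
                     !is.na(maf_l) & maf_l > 0)
  pooled <- NA_real_
  if (length(seg_phr)) {
    X <- pair$left$calls[, seg_phr, drop = FALSE]
    Y <- pair$right$calls[, seg_phr, drop = FALSE]
    pooled <- genotype_concordance(as.vector(X), as.vector(Y))
  }
  list(table = out, poly_high_res_pooled_gc = pooled)
}

#' Quality scores of concordant versus discordant genotypes
#'
#' Splits pairwise-complete genotype cells into concordant and discordant
#' and compares their quality scores with a Welch two-sample two-sided
#' t-test. The per-cell score is the tested platform's score, or, for
#' duplicate runs where both sides carry quality (`platform = "min"`), the
#' minimum of the two replicates' scores.
#'
#' @param pair an [aligned_pair()].
#' @param platform `"left"`, `"right"`, or `"min"` (elementwise minimum of
#'   both platforms' scores).
#' @return object of class `quality_comparison`: list with
#'   `mean_quality_concordant`, `mean_quality_discordant`, `n_concordant`,
#'   `n_discordant`, `t_statistic`, `p_value`.
#' @export
quality_mean_comparison <- function(pair, platform = c("left", "right", "min")) {
  platform <- match.arg(platform)
  q <- switch(platform,
    left = pair$left$quality,
    right = pair$right$quality,
    min = {
      if (is.null(pair$left$quality) || is.null(pair$right$quality)) {
        stop_pipeline("platform = 'min' requires quality on both platforms")
      }
      pmin(pair$left$quality, pair$right$quality)
    }
  )
  if (is.null(q)) stop_pipeline("chosen platform carries no quality scores")
  ok <- !is.na(pair$left$calls) & !is.na(pair$right$calls) & !is.na(q)
  conc <- pair$left$calls == pair$right$calls
  q_c <- q[which(ok & conc)]
  q_d <- q[which(ok & !conc)]
  res <- list(mean_quality_concordant = if (length(q_c)) mean(q_c) else NA_real_,
              mean_quality_discordant = if (length(q_d)) mean(q_d) else NA_real_,
              n_concordant = length(q_c), n_discordant = length(q_d),
              t_statistic = NA_real_, p_value = NA_real_)
  if (length(q_c) < 2L || length(q_d) < 2L ||
      (stats::var(q_c) == 0 && stats::var(q_d) == 0)) {
    if (length(q_c) == 0L || length(q_d) == 0L) {
      warning("a concordance group is empty; quality comparison is NA")
    }
    return(structure(res, class = "quality_comparison"))
  }
  tt <- stats::t.test(q_c, q_d, var.equal = FALSE)
  res$t_statistic <- unname(tt$statistic)
  res$p_value <- tt$p.value
  structure(res, class = "quality_comparison")
}

#' @export
print.quality_comparison <- function(x, ...) {
  cat(sprintf("Mean quality: concordant %.4f (n=%d), discordant %.4f (n=%d)\n",
              x$mean_quality_concordant, x$n_concordant,
              x$mean_quality_discordant, x$n_discordant))
  cat(sprintf("Welch t = %.3f, p = %.3g\n", x$t_statistic, x$p_value))
  invisible(x)
}
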