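#' Run the full concordance analysis
#'
#' Orchestrates the whole comparison: harmonize the two call sets (SNP
#' intersection, allele-coding reconciliation, sample call-rate filtering),
#' then compute per-animal, per-SNP and pooled concordance statistics, the
#' genotype contingency table, MAF / quality / category stratifications,
#' the concordant-versus-discordant quality comparison, and the effect of
#' masking low-quality calls. Either two datasets or a simulator
#' configuration (whose aligned pair is analysed directly) must be given.
#'
#' @param left,right [platform_dataset()]s over overlapping samples/SNPs.
#' @param sim_config alternatively, a [simulation_config()].
#' @param drop_ids SNP ids excluded up front (see [match_snps()]).
#' @param call_rate_threshold sample call-rate threshold; default 0.90.
#' @param quality_threshold score below (GC) or above (confidence) which
#'   calls are masked in the quality-restriction step; default 0.55.
#' @param min_allele_concordance per-SNP allele-concordance threshold for
#'   the filtered summary; default 0.80.
#' @param maf_bin_width MAF stratification bin width; default 0.05.
#' @param quality_bins bin edges for quality stratification.
#' @return object of class `concordance_report`: list with elements
#'   `pair`, `audit`, `per_animal`, `per_snp`, `overall`, `headline`,
#'   `contingency`, `maf_strata`, `quality_strata`, `category`,
#'   `quality_comparison`, `quality_restriction`, `concordance_filter`.
#' @export
run_pipeline <- function(left = NULL, right = NULL, sim_config = NULL,
                         drop_ids = character(),
                         call_rate_threshold = 0.9,
                         quality_threshold = 0.55,
                         min_allele_concordance = 0.8,
                         maf_bin_width = 0.05,
                         quality_bins = seq(0, 1, by = 0.05)) {
  have_data <- !is.null(left) && !is.null(right)
  if (have_data == !is.null(sim_config)) {
    stop_config("supply either two datasets or a simulator configuration, not both")
  }
  if (!is.null(sim_config)) {
    pair <- simulate_dual_platform(sim_config)$pair
    audit <- filter_audit(
      n_snps_initial_left = nrow(pair$left$snps),
      n_snps_initial_right = nrow(pair$right$snps),
      n_snps_common = nrow(pair$left$snps),
      n_samples_initial = length(pair$left$sample_ids),
      n_samples_retained = length(pair$left$sample_ids),
      call_rate_threshold = call_rate_threshold
    )
    pair$audit <- audit
  } else {
    pair <- harmonize_pair(left, right, drop_ids, call_rate_threshold)
  }

  per_animal <- summarize_concordance(pair, "animal")
  per_snp <- summarize_concordance(pair, "snp")
  overall <- summarize_concordance(pair, "overall")
  headline <- concordance_overview(per_animal)
  contingency <- contingency_table(pair)
  maf_strata <- stratify_by_maf(pair, per_snp, "left", maf_bin_width)

  quality_strata <- NULL
  quality_comparison <- NULL
  quality_restriction <- NULL
  q_platform <- if (!is.null(pair$left$quality)) "left" else
    if (!is.null(pair$right$quality)) "right" else NULL
  if (!is.null(q_platform)) {
    quality_strata <- stratify_by_quality(pair, per_snp, q_platform, quality_bins)
    quality_comparison <- quality_mean_comparison(pair, q_platform)
    restricted <- tryCatch(
      restrict_by_quality(pair, q_platform, quality_threshold),
      pipeline_error = function(e) NULL
    )
    if (!is.null(restricted)) {
      quality_restriction <- list(
        platform = q_platform,
        threshold = quality_threshold,
        allele_concordance_before = overall$allele_concordance,
        allele_concordance_after =
          summarize_concordance(restricted, "overall")$allele_concordance
      )
    }
  }

  category <- NULL
  if (any(!is.na(pair$right$snps$category))) {
    category <- category_summary(pair, per_snp)
  }

  kept <- suppressMessages(
    tryCatch(filter_snps_by_concordance(pair, per_snp, min_allele_concordance),
             pipeline_error = function(e) NULL)
  )
  concordance_filter <- NULL
  if (!is.null(kept)) {
    kept_snp <- summarize_concordance(kept, "snp")
    concordance_filter <- list(
      min_allele_concordance = min_allele_concordance,
      n_snps_before = nrow(per_snp),
      n_snps_after = nrow(kept_snp),
      mean_genotype_concordance_after = mean(kept_snp$genotype_concordance, na.rm = TRUE),
      mean_allele_concordance_after = mean(kept_snp$allele_concordance, na.rm = TRUE)
    )
  }

  structure(list(
    pair = pair, audit = pair$audit,
    per_animal = per_animal, per_snp = per_snp, overall = overall,
    headline = headline, contingency = contingency,
    maf_strata = maf_strata, quality_strata = quality_strata,
    category = category, quality_comparison = quality_comparison,
    quality_restriction = quality_restriction,
    concordance_filter = concordance_filter
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance report\n")
  print(x$audit)
  cat("Per-animal headline (mean [min, max]):\n")
  h <- x$headline
  for (i in seq_len(nrow(h))) {
    cat(sprintf("  %-22s %.4f [%.4f, %.4f]\n",
                h$statistic[i], h$mean[i], h$min[i], h$max[i]))
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

fmt_rate <- function(x) formatC(x, digits = 4, format = "f")
fmt_pct <- function(x) formatC(x, digits = 2, format = "f")

#' Write a concordance report to disk
#'
#' Renders a [run_pipeline()] bundle as machine-readable TSV tables (full
#' precision) plus a human-readable `report.md` (rates to 4 decimals,
#' percentages to 2, the contingency table in 3 x 3 row-percent layout).
#' Output is deterministic for a given bundle; empty sections are omitted
#' from the markdown with a note.
#'
#' @param bundle a `concordance_report` from [run_pipeline()].
#' @param dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_tsv(bundle$per_animal, file.path(dir, "per_animal.tsv")),
    write_tsv(bundle$per_snp, file.path(dir, "per_snp.tsv")),
    write_tsv(bundle$overall, file.path(dir, "overall.tsv")),
    write_tsv(bundle$maf_strata, file.path(dir, "maf_strata.tsv"))
  )
  if (!is.null(bundle$quality_strata)) {
    files <- c(files, write_tsv(bundle$quality_strata,
                                file.path(dir, "quality_strata.tsv")))
  }
  if (!is.null(bundle$category)) {
    files <- c(files, write_tsv(bundle$category$table,
                                file.path(dir, "category_strata.tsv")))
  }
  ct <- bundle$contingency
  counts_df <- data.frame(left_genotype = 0:2, ct$counts)
  names(counts_df)[2:4] <- paste0("right_", 0:2)
  files <- c(files, write_tsv(counts_df, file.path(dir, "contingency_counts.tsv")))

  md <- c("# Genotype concordance report", "")
  a <- bundle$audit
  md <- c(md, "## Filter accounting", "",
          sprintf("- SNPs: %s (left) / %s (right) initial, %s common, %s dropped as unresolvable",
                  a$n_snps_initial_left, a$n_snps_initial_right,
                  a$n_snps_common, a$n_snps_dropped_unresolvable),
          sprintf("- Samples: %s shared, %s retained at call rate >= %s (failing left: %s; right: %s)",
                  a$n_samples_initial, a$n_samples_retained, a$call_rate_threshold,
                  length(a$samples_failing_left), length(a$samples_failing_right)),
          "")
  h <- bundle$headline
  md <- c(md, "## Per-animal summary (mean [min, max])", "",
          sprintf("- %s: %s [%s, %s]", h$statistic,
                  fmt_rate(h$mean), fmt_rate(h$min), fmt_rate(h$max)),
          "",
          "## Pooled over all compared cells", "",
          sprintf("- genotype concordance %s, allele concordance %s over %d cells",
                  fmt_rate(bundle$overall$genotype_concordance),
                  fmt_rate(bundle$overall$allele_concordance),
                  bundle$overall$n_compared),
          "")
  rp <- ct$row_percent
  md <- c(md, "## Genotype contingency (row %)", "",
          "| left \\ right | 0 | 1 | 2 |", "|---|---|---|---|",
          sprintf("| %d | %s | %s | %s |", 0:2,
                  fmt_pct(rp[, 1]), fmt_pct(rp[, 2]), fmt_pct(rp[, 3])),
          "",
          sprintf("Opposite-homozygote proportion: %s%% (of left homozygotes), %s%% (of right homozygotes)",
                  fmt_pct(100 * ct$opposite_hom_prop_left),
                  fmt_pct(100 * ct$opposite_hom_prop_right)),
          "")
  if (!is.null(bundle$quality_comparison)) {
    qc <- bundle$quality_comparison
    md <- c(md, "## Quality of concordant vs discordant genotypes", "",
            sprintf("- mean quality %s (concordant, n = %d) vs %s (discordant, n = %d); Welch p = %.3g",
                    fmt_rate(qc$mean_quality_concordant), qc$n_concordant,
                    fmt_rate(qc$mean_quality_discordant), qc$n_discordant,
                    qc$p_value),
            "")
  } else {
    md <- c(md, "_Quality sections omitted: no quality scores present._", "")
  }
  if (!is.null(bundle$quality_restriction)) {
    qr <- bundle$quality_restriction
    md <- c(md, sprintf("Masking %s-platform calls at quality threshold %s changed pooled allele concordance from %s to %s.",
                        qr$platform, qr$threshold,
                        fmt_rate(qr$allele_concordance_before),
                        fmt_rate(qr$allele_concordance_after)),
            "")
  }
  if (!is.null(bundle$concordance_filter)) {
    cf <- bundle$concordance_filter
    md <- c(md, sprintf("Excluding SNPs with allele concordance < %s kept %d of %d SNPs; mean per-SNP genotype (allele) concordance %s (%s).",
                        cf$min_allele_concordance, cf$n_snps_after, cf$n_snps_before,
                        fmt_rate(cf$mean_genotype_concordance_after),
                        fmt_rate(cf$mean_allele_concordance_after)),
            "")
  }
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  invisible(c(files, md_path))
}
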