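#' SNP record table
#'
#' Builds the per-SNP metadata table used inside a [platform_dataset()]:
#' SNP identifier, map position and the two allele letters, with an optional
#' Axiom-style cluster-quality category label.
#'
#' Genotypes are stored as counts of `allele_b` (0 = AA, 1 = AB, 2 = BB in
#' the A/B convention), so `allele_a`/`allele_b` define the meaning of every
#' call in the dataset. Allele letters may be `NA` when a call table carries
#' no allele information; such SNPs are assumed to share one coding across
#' platforms and are never strand-flipped.
#'
#' @param snp_id character, unique SNP identifiers.
#' @param chrom character chromosome labels (recycled).
#' @param pos non-negative integer 1-based map positions (recycled).
#' @param allele_a,allele_b single bases in A/C/G/T (or `NA`); must differ
#'   where both are present.
#' @param category optional per-SNP label, one of the six Axiom
#'   cluster-quality categories (see [snp_categories()]), or `NA`.
#' @return data.frame with one row per SNP.
#' @export
snp_records <- function(snp_id, chrom = "0", pos = 0L,
                        allele_a = NA_character_, allele_b = NA_character_,
                        category = NA_character_) {
  n <- length(snp_id)
  df <- data.frame(
    snp_id   = as.character(snp_id),
    chrom    = rep_len(as.character(chrom), n),
    pos      = rep_len(as.integer(pos), n),
    allele_a = rep_len(as.character(allele_a), n),
    allele_b = rep_len(as.character(allele_b), n),
    category = rep_len(as.character(category), n),
    stringsAsFactors = FALSE
  )
  validate_snp_records(df)
  df
}

#' Recognised Axiom SNP cluster-quality categories
#'
#' The six cluster-quality labels assigned by the Affymetrix Axiom analysis
#' software: three well-resolved genotype clusters (PolyHighResolution), two
#' clusters with a missing minor homozygote (NoMinorHom), all calls
#' monomorphic (MonoHighResolution), an extra off-target cluster
#' (OffTargetVariant), call rate below threshold with good clusters
#' (CallRateBelowThres), and everything else (Other).
#'
#' @return character vector of the six labels.
#' @export
snp_categories <- function() {
  c("PolyHighResolution", "NoMinorHom", "MonoHighResolution",
    "OffTargetVariant", "CallRateBelowThres", "Other")
}

validate_snp_records <- function(df) {
  if (anyDuplicated(df$snp_id)) {
    dup <- df$snp_id[duplicated(df$snp_id)][1L]
    stop_data("duplicate snp_id '%s'", dup)
  }
  if (any(df$pos < 0L, na.rm = TRUE)) stop_data("negative map position")
  bases <- c("A", "C", "G", "T")
  bad_a <- !is.na(df$allele_a) & !(df$allele_a %in% bases)
  bad_b <- !is.na(df$allele_b) & !(df$allele_b %in% bases)
  if (any(bad_a) || any(bad_b)) {
    stop_data("allele letters must be one of A/C/G/T (snp '%s')",
              df$snp_id[which(bad_a | bad_b)[1L]])
  }
  same <- !is.na(df$allele_a) & !is.na(df$allele_b) & df$allele_a == df$allele_b
  if (any(same)) {
    stop_data("allele_a equals allele_b at snp '%s'", df$snp_id[which(same)[1L]])
  }
  bad_cat <- !is.na(df$category) &
    !(df$category %in% c(snp_categories(), "Unlabelled"))
  if (any(bad_cat)) {
    stop_data("unknown SNP category '%s'", df$category[which(bad_cat)[1L]])
  }
  invisible(df)
}

#' Genotype call set from one platform
#'
#' Container for a sample-by-SNP matrix of allele counts with optional
#' per-call quality scores, the unit every comparison in this package
#' operates on. Calls are counts of the B allele: 0 = AA, 1 = AB, 2 = BB;
#' a missing call is `NA`. Quality scores are per-call, non-negative reals;
#' `quality_orientation` records whether larger scores mean better calls
#' (Illumina GenCall GC score) or worse calls (Affymetrix confidence score).
#'
#' @param platform_name label for the platform/run.
#' @param sample_ids unique sample identifiers, one per matrix row.
#' @param snps SNP metadata from [snp_records()], one row per matrix column.
#' @param calls integer matrix of allele counts in \{0, 1, 2, NA\}.
#' @param quality optional numeric matrix of per-call scores, same shape as
#'   `calls`; every non-missing call must have a score.
#' @param quality_orientation `"higher_is_better"` or `"lower_is_better"`.
#' @return object of class `platform_dataset`.
#' @export
platform_dataset <- function(platform_name, sample_ids, snps, calls,
                             quality = NULL,
                             quality_orientation = c("higher_is_better",
                                                     "lower_is_better")) {
  quality_orientation <- match.arg(quality_orientation)
  sample_ids <- as.character(sample_ids)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(sample_ids, snps$snp_id)
  if (!is.null(quality)) {
    quality <- as.matrix(quality)
    storage.mode(quality) <- "double"
    dimnames(quality) <- dimnames(calls)
  }
  ds <- structure(
    list(platform_name = as.character(platform_name)[1L],
         sample_ids = sample_ids, snps = snps, calls = calls,
         quality = quality, quality_orientation = quality_orientation),
    class = "platform_dataset"
  )
  validate_platform_dataset(ds)
  ds
}

validate_platform_dataset <- function(ds) {
  validate_snp_records(ds$snps)
  if (anyDuplicated(ds$sample_ids)) stop_data("duplicate sample ids")
  if (nrow(ds$calls) != length(ds$sample_ids) ||
      ncol(ds$calls) != nrow(ds$snps)) {
    stop_data("calls matrix is %d x %d but dataset declares %d samples and %d SNPs",
              nrow(ds$calls), ncol(ds$calls),
              length(ds$sample_ids), nrow(ds$snps))
  }
  vals <- ds$calls[!is.na(ds$calls)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop_data("calls must be 0, 1, 2 or NA")
  }
  if (!is.null(ds$quality)) {
    if (!identical(dim(ds$quality), dim(ds$calls))) {
      stop_data("quality matrix shape differs from calls")
    }
    uncovered <- !is.na(ds$calls) & is.na(ds$quality)
    if (any(uncovered)) {
      stop_data("non-missing calls without a quality score")
    }
    if (any(ds$quality < 0, na.rm = TRUE)) stop_data("negative quality score")
  }
  invisible(ds)
}

#' @export
print.platform_dataset <- function(x, ...) {
  cat(sprintf("<platform_dataset '%s': %d samples x %d SNPs, quality %s (%s)>\n",
              x$platform_name, length(x$sample_ids), nrow(x$snps),
              if (is.null(x$quality)) "absent" else "present",
              x$quality_orientation))
  invisible(x)
}

#' @export
dim.platform_dataset <- function(x) dim(x$calls)

# Restrict a dataset to given samples/snps (by id), preserving order of the
# index vectors; used by all matching and filtering steps.
subset_dataset <- function(ds, sample_ids = NULL, snp_ids = NULL) {
  ri <- if (is.null(sample_ids)) seq_along(ds$sample_ids) else {
    i <- match(sample_ids, ds$sample_ids)
    if (anyNA(i)) stop_lookup("unknown sample id '%s'", sample_ids[which(is.na(i))[1L]])
    i
  }
  ci <- if (is.null(snp_ids)) seq_len(nrow(ds$snps)) else {
    j <- match(snp_ids, ds$snps$snp_id)
    if (anyNA(j)) stop_lookup("unknown snp id '%s'", snp_ids[which(is.na(j))[1L]])
    j
  }
  ds$sample_ids <- ds$sample_ids[ri]
  ds$snps <- ds$snps[ci, , drop = FALSE]
  rownames(ds$snps) <- NULL
  ds$calls <- ds$calls[ri, ci, drop = FALSE]
  if (!is.null(ds$quality)) ds$quality <- ds$quality[ri, ci, drop = FALSE]
  ds
}

#' Matched pair of call sets
#'
#' Two [platform_dataset()]s restricted to common samples and common,
#' coding-reconciled SNPs, in identical order, plus the [filter_audit()]
#' accumulated while matching. All concordance statistics operate on this.
#'
#' @param left,right matched datasets with identical sample and SNP order.
#' @param audit a `filter_audit`, or `NULL`.
#' @return object of class `aligned_pair`.
#' @export
aligned_pair <- function(left, right, audit = NULL) {
  if (!identical(left$sample_ids, right$sample_ids)) {
    stop_data("aligned pair requires identical sample order")
  }
  if (!identical(left$snps$snp_id, right$snps$snp_id)) {
    stop_data("aligned pair requires identical SNP order")
  }
  structure(list(left = left, right = right, audit = audit),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair '%s' vs '%s': %d samples x %d SNPs>\n",
              x$left$platform_name, x$right$platform_name,
              length(x$left$sample_ids), nrow(x$left$snps)))
  invisible(x)
}
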