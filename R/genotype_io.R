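#' Read a PLINK text PED/MAP pair
#'
#' Parses space-delimited PLINK text files into a [platform_dataset()].
#' Each PED row carries six leading columns (family, individual, sire, dam,
#' sex, phenotype) followed by one allele pair per MAP row; `0 0` allele
#' pairs become missing calls. Unless a `manifest` supplies the A/B letters,
#' `allele_a` is the major and `allele_b` the minor observed allele at each
#' SNP (ties at frequency 0.5 broken alphabetically), and calls store the
#' count of `allele_b`. A SNP observed with more than two distinct alleles
#' is a data error.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param platform_name label for the resulting dataset.
#' @param manifest optional data.frame with columns `snp_id`, `allele_a`,
#'   `allele_b` fixing the coding instead of the observed major/minor rule.
#' @return a [platform_dataset()] without quality scores.
#' @export
read_plink_text <- function(ped_path, map_path, platform_name,
                            manifest = NULL) {
  if (!file.exists(ped_path)) stop_parse("PED file not found: %s", ped_path)
  if (!file.exists(map_path)) stop_parse("MAP file not found: %s", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nfld <- lengths(map_tok)
  if (any(nfld < 4L)) {
    stop_parse("MAP line %d: expected 4 fields, found %d",
               which(nfld < 4L)[1L], nfld[which(nfld < 4L)[1L]])
  }
  map <- do.call(rbind, lapply(map_tok, `[`, 1:4))
  n_snps <- nrow(map)
  pos <- suppressWarnings(as.integer(map[, 4L]))
  if (anyNA(pos)) stop_parse("MAP line %d: non-integer position", which(is.na(pos))[1L])

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * n_snps
  nfld <- lengths(ped_tok)
  if (any(nfld != want)) {
    bad <- which(nfld != want)[1L]
    stop_parse("PED line %d: expected %d fields, found %d", bad, want, nfld[bad])
  }
  n_samples <- length(ped_tok)
  if (n_samples == 0L) stop_parse("PED file is empty")
  tok <- matrix(unlist(ped_tok), nrow = n_samples, byrow = TRUE)
  sample_ids <- tok[, 2L]

  a1 <- tok[, 6L + 2L * seq_len(n_snps) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(n_snps), drop = FALSE]
  ok_tok <- c("A", "C", "G", "T", "0")
  bad <- !(a1 %in% ok_tok) | !(a2 %in% ok_tok)
  if (any(bad)) {
    stop_parse("PED line %d: allele token must be A/C/G/T or 0",
               ((which(bad)[1L] - 1L) %% n_samples) + 1L)
  }
  half_missing <- xor(a1 == "0", a2 == "0")
  if (any(half_missing)) {
    stop_parse("PED line %d: half-missing allele pair",
               ((which(half_missing)[1L] - 1L) %% n_samples) + 1L)
  }
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  allele_a <- character(n_snps)
  allele_b <- character(n_snps)
  calls <- matrix(NA_integer_, n_samples, n_snps)
  man_idx <- if (is.null(manifest)) rep(NA_integer_, n_snps) else
    match(map[, 2L], manifest$snp_id)
  for (j in seq_len(n_snps)) {
    obs <- c(a1[, j], a2[, j])
    lev <- sort(unique(obs[!is.na(obs)]))
    if (length(lev) > 2L) {
      stop_data("SNP '%s': more than two observed alleles (%s)",
                map[j, 2L], paste(lev, collapse = "/"))
    }
    if (!is.na(man_idx[j])) {
      aa <- manifest$allele_a[man_idx[j]]
      bb <- manifest$allele_b[man_idx[j]]
      if (length(setdiff(lev, c(aa, bb)))) {
        stop_data("SNP '%s': observed allele outside manifest %s/%s",
                  map[j, 2L], aa, bb)
      }
    } else if (length(lev) == 0L) {
      aa <- "A"; bb <- "C"   # fully missing SNP: coding unidentifiable
    } else if (length(lev) == 1L) {
      aa <- lev
      bb <- setdiff(c("A", "C", "G", "T"), aa)[1L]
    } else {
      f1 <- sum(obs == lev[1L], na.rm = TRUE)
      f2 <- sum(obs == lev[2L], na.rm = TRUE)
      # major allele is allele_a; alphabetical order (lev is sorted) on ties
      if (f1 >= f2) { aa <- lev[1L]; bb <- lev[2L] }
      else          { aa <- lev[2L]; bb <- lev[1L] }
    }
    allele_a[j] <- aa
    allele_b[j] <- bb
    calls[, j] <- (a1[, j] == bb) + (a2[, j] == bb)
  }

  snps <- snp_records(snp_id = map[, 2L], chrom = map[, 1L], pos = pos,
                      allele_a = allele_a, allele_b = allele_b)
  platform_dataset(platform_name, sample_ids, snps, calls)
}

#' Read a long-format genotype call table
#'
#' Reads a UTF-8 TSV with header columns `sample_id`, `snp_id`, `call`
#' (0/1/2/NA) and optionally `quality`, into a [platform_dataset()].
#' Optional `#`-prefixed header lines written by [write_call_table()]
#' declare the platform, quality orientation, the full sample list and
#' per-SNP metadata, so that samples or SNPs with no called genotypes are
#' preserved. Cells absent from the table are missing calls; a duplicated
#' (sample, SNP) cell is a data error.
#'
#' @param path file path.
#' @param platform_name dataset label; defaults to the file's `#platform`
#'   header when present.
#' @param quality_orientation `"higher_is_better"` or `"lower_is_better"`;
#'   defaults to the file header, else higher-is-better.
#' @return a [platform_dataset()].
#' @export
read_call_table <- function(path, platform_name = NULL,
                            quality_orientation = NULL) {
  if (!file.exists(path)) stop_parse("call table not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  body <- lines[!hdr]

  get_meta <- function(key) {
    m <- meta[startsWith(meta, paste0("#", key, " "))]
    sub(paste0("^#", key, " "), "", m)
  }
  if (is.null(platform_name)) {
    platform_name <- if (length(get_meta("platform"))) get_meta("platform")[1L] else "unknown"
  }
  if (is.null(quality_orientation)) {
    qo <- get_meta("quality_orientation")
    quality_orientation <- if (length(qo)) qo[1L] else "higher_is_better"
  }

  if (!length(body)) stop_parse("call table '%s' has no data section", path)
  head_fields <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (!all(c("sample_id", "snp_id", "call") %in% head_fields)) {
    stop_parse("call table '%s': header must contain sample_id, snp_id, call", path)
  }
  df <- if (length(body) > 1L) {
    utils::read.table(text = body, header = TRUE, sep = "\t",
                      colClasses = "character", na.strings = "NA",
                      quote = "", comment.char = "")
  } else {
    stats::setNames(as.data.frame(matrix(character(), 0, length(head_fields))),
                    head_fields)
  }

  calls_num <- suppressWarnings(as.integer(df$call))
  bad <- !is.na(df$call) & (is.na(calls_num) | !(calls_num %in% 0:2))
  if (any(bad)) {
    stop_parse("call table '%s': call value '%s' outside 0/1/2/NA",
               path, df$call[which(bad)[1L]])
  }
  has_quality <- "quality" %in% names(df)
  qual_num <- if (has_quality) suppressWarnings(as.numeric(df$quality)) else NULL

  sample_ids <- get_meta("sample")
  if (!length(sample_ids)) sample_ids <- unique(df$sample_id)
  snp_meta <- get_meta("snp")
  if (length(snp_meta)) {
    tok <- strsplit(snp_meta, "\t", fixed = TRUE)
    if (any(lengths(tok) != 6L)) stop_parse("malformed #snp header line")
    tok <- do.call(rbind, tok)
    tok[tok == "NA"] <- NA
    snps <- snp_records(snp_id = tok[, 1L], chrom = tok[, 2L],
                        pos = as.integer(tok[, 3L]),
                        allele_a = tok[, 4L], allele_b = tok[, 5L],
                        category = tok[, 6L])
  } else {
    snps <- snp_records(snp_id = unique(df$snp_id))
  }

  ri <- match(df$sample_id, sample_ids)
  ci <- match(df$snp_id, snps$snp_id)
  if (anyNA(ri)) stop_data("call table row references undeclared sample '%s'",
                           df$sample_id[which(is.na(ri))[1L]])
  if (anyNA(ci)) stop_data("call table row references undeclared snp '%s'",
                           df$snp_id[which(is.na(ci))[1L]])
  cell <- (ci - 1L) * length(sample_ids) + ri
  if (anyDuplicated(cell)) {
    d <- which(duplicated(cell))[1L]
    stop_data("duplicate cell for sample '%s', snp '%s'",
              df$sample_id[d], df$snp_id[d])
  }
  calls <- matrix(NA_integer_, length(sample_ids), nrow(snps))
  calls[cell] <- calls_num
  quality <- NULL
  if (has_quality) {
    quality <- matrix(NA_real_, length(sample_ids), nrow(snps))
    quality[cell] <- qual_num
  }
  platform_dataset(platform_name, sample_ids, snps, calls, quality,
                   quality_orientation)
}

#' Write a dataset as a long call table
#'
#' Serialises a [platform_dataset()] to the TSV accepted by
#' [read_call_table()]. A `#`-prefixed header block records the platform
#' name, quality orientation, every sample (including samples with no
#' called genotype) and per-SNP metadata; the body holds one row per
#' non-missing call. The round trip through [read_call_table()] reproduces
#' identifiers, calls and quality exactly.
#'
#' @param ds a valid [platform_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(ds, path) {
  validate_platform_dataset(ds)
  if (nrow(ds$snps) == 0L) stop_data("refusing to write a dataset with no SNPs")
  snp_lines <- sprintf("#snp %s", apply(cbind(
    ds$snps$snp_id, ds$snps$chrom, ds$snps$pos,
    ds$snps$allele_a, ds$snps$allele_b, ds$snps$category
  ), 1L, paste, collapse = "\t"))
  header <- c(
    sprintf("#platform %s", ds$platform_name),
    sprintf("#quality_orientation %s", ds$quality_orientation),
    sprintf("#sample %s", ds$sample_ids),
    snp_lines
  )
  keep <- which(!is.na(ds$calls))
  ri <- ((keep - 1L) %% nrow(ds$calls)) + 1L
  ci <- ((keep - 1L) %/% nrow(ds$calls)) + 1L
  if (is.null(ds$quality)) {
    body_head <- "sample_id\tsnp_id\tcall"
    rows <- sprintf("%s\t%s\t%d", ds$sample_ids[ri], ds$snps$snp_id[ci],
                    ds$calls[keep])
  } else {
    body_head <- "sample_id\tsnp_id\tcall\tquality"
    rows <- sprintf("%s\t%s\t%d\t%s", ds$sample_ids[ri], ds$snps$snp_id[ci],
                    ds$calls[keep],
                    formatC(ds$quality[keep], digits = 17, format = "g"))
  }
  con <- try(file(path, open = "wt", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) stop_parse("cannot open '%s' for writing", path)
  on.exit(close(con))
  writeLines(c(header, body_head, rows), con)
  invisible(path)
}
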