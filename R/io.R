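# Readers and writers for the pipeline's plain-text formats.  Genomic
# tables use 1-based bp positions; BED output is 0-based half-open.

#' Read an allele-count table
#'
#' Tab-separated with columns `CHROM`, `POS` (1-based), `REF`, `ALT`,
#' `HIGH_REF`, `HIGH_ALT`, `LOW_REF`, `LOW_ALT`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_allele_counts <- function(path) {
  hdr <- names(utils::read.delim(path, nrows = 1))
  cls <- rep(NA, length(hdr))
  # single-base alleles like "T" must not be parsed as logical
  cls[hdr %in% c("REF", "ALT")] <- "character"
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = cls)
  need <- c("CHROM", "POS", "HIGH_REF", "HIGH_ALT", "LOW_REF", "LOW_ALT")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("allele-count file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_allele_counts
#' @param counts allele-count data.frame.
#' @export
write_allele_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read bulk allele depths from a minimal VCF
#'
#' Accepts a biallelic VCF whose genotype field includes `AD` (comma
#' separated ref,alt depths) for two samples; the first sample is taken as
#' the high bulk and the second as the low bulk unless sample names are
#' given.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param high,low sample names (default: first and second sample).
#' @return allele-count data.frame as from [read_allele_counts()].
#' @export
read_allele_counts_vcf <- function(path, high = NULL, low = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (ncol(ad) < 2) stop("VCF must contain two bulk samples", call. = FALSE)
  if (is.null(high)) high <- colnames(ad)[1]
  if (is.null(low)) low <- colnames(ad)[2]
  split_ad <- function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad & !is.na(v))) {
      stop("multi-allelic AD entries are not supported; drop them upstream",
           call. = FALSE)
    }
    ref <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    alt <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    list(ref = ref, alt = alt)
  }
  hi <- split_ad(ad[, high])
  lo <- split_ad(ad[, low])
  fix <- vcfR::getFIX(vcf)
  data.frame(
    CHROM = fix[, "CHROM"], POS = as.integer(fix[, "POS"]),
    REF = fix[, "REF"], ALT = fix[, "ALT"],
    HIGH_REF = hi$ref, HIGH_ALT = hi$alt,
    LOW_REF = lo$ref, LOW_ALT = lo$alt
  )
}

#' Write candidate regions
#'
#' `write_regions_bed()` writes 0-based half-open BED;
#' `write_regions_tsv()` writes the 1-based summary table (physical
#' interval, delta range, significance level).
#'
#' @param regions data.frame from [call_candidate_regions()].
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines("# BED: 0-based, half-open intervals (no regions called)", path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = regions$CHROM,
    start = format(pmax(0, regions$start), scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE),
    name = sprintf("region_%d", seq_len(nrow(regions))),
    score = round(abs(regions$peak_delta) * 1000),
    strand = "."
  )
  con <- file(path, "w")
  writeLines("# BED: 0-based, half-open intervals", con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
write_regions_tsv <- function(regions, path) {
  out <- data.frame(
    chrom = regions$CHROM,
    start_bp = regions$start + 1, # table convention: 1-based inclusive
    end_bp = regions$end,
    delta_range = sprintf("%.2f-%.2f", regions$delta_min, regions$delta_max),
    peak_delta = round(regions$peak_delta, 4),
    direction = regions$direction,
    level = regions$level
  )
  con <- file(path, "w")
  writeLines("# 1-based inclusive bp intervals", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Genotype matrix CSV
#'
#' Rows are individuals (first column `id`), remaining columns markers with
#' codes A/H/B/`-`.
#'
#' @param path file path.
#' @return list with `geno` (character matrix) and `id`.
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  id <- df[[1]]
  geno <- as.matrix(df[, -1, drop = FALSE])
  bad <- !(geno %in% c("A", "H", "B", "-"))
  if (any(bad)) stop("genotype codes outside A/H/B/-", call. = FALSE)
  list(id = id, geno = geno)
}

#' @rdname read_genotype_csv
#' @param geno character matrix of codes, columns named by marker.
#' @param id individual ids.
#' @export
write_genotype_csv <- function(geno, id, path) {
  df <- data.frame(id = id, geno, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Phenotype CSV (`id`, `peds_percent`)
#'
#' @param path file path.
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "peds_percent") %in% names(df)))
  df
}

#' @rdname read_phenotype_csv
#' @param phenotypes data.frame `id`, `peds_percent`.
#' @export
write_phenotype_csv <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Genetic map TSV (`marker`, `chrom`, `pos_bp`, `pos_cM`)
#'
#' @param path file path.
#' @export
read_map_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_map_tsv
#' @param map `genetic_map` data.frame.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Threshold-curve TSV keyed by depth
#'
#' @param curve a `threshold_curve`.
#' @param path file path.
#' @export
write_threshold_tsv <- function(curve, path) {
  con <- file(path, "w")
  writeLines(sprintf("# design=%s n_high=%d n_low=%d n_reps=%d",
                     attr(curve, "design"), attr(curve, "n_high"),
                     attr(curve, "n_low"), attr(curve, "n_reps")), con)
  utils::write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}
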