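# Pipeline orchestration: phenotype summaries and the end-to-end
# simulate -> snp-index -> thresholds -> regions -> map -> scans chain.

#' PEDS from cupule counts
#'
#' PEDS is the percentage of cupules bearing a single (unpaired) spikelet.
#'
#' @param single_spikelet_cupules cupules without a pedicellate spikelet.
#' @param total_cupules total cupules scored (> 0).
#' @return `100 * single / total`.
#' @export
compute_peds <- function(single_spikelet_cupules, total_cupules) {
  if (any(total_cupules <= 0)) {
    stop("total cupule count must be positive", call. = FALSE)
  }
  if (any(single_spikelet_cupules < 0 |
            single_spikelet_cupules > total_cupules)) {
    stop("single-spikelet count must lie in [0, total]", call. = FALSE)
  }
  100 * single_spikelet_cupules / total_cupules
}

#' Descriptive summary of a PEDS distribution
#'
#' Bins plants into the class 0% (exact) and the upper-closed classes
#' (0,10], (10,20], ..., (90,100], and reports the total, the mean PEDS,
#' and the ratio total : plants-with-PEDS>0 (to 2 decimals; missing when no
#' plant has PEDS > 0).
#'
#' @param peds numeric vector of PEDS percentages in [0, 100].
#' @param environment optional environment label.
#' @return list of class `peds_summary` with `environment`, `bins`
#'   (named counts), `total`, `mean`, `ratio`.
#' @export
summarize_phenotypes <- function(peds, environment = NA_character_) {
  if (any(peds < 0 | peds > 100, na.rm = TRUE)) {
    stop("PEDS must lie in [0, 100]", call. = FALSE)
  }
  peds <- peds[!is.na(peds)]
  edges <- seq(0, 100, by = 10)
  pos <- peds[peds > 0]
  cls <- cut(pos, edges, include.lowest = FALSE) # (0,10], ..., (90,100]
  bins <- c("0%" = sum(peds == 0), table(cls))
  n0 <- sum(peds == 0)
  total <- length(peds)
  ratio <- if (total > n0) round(total / (total - n0), 2) else NA_real_
  structure(
    list(environment = environment, bins = bins, total = total,
         mean = mean(peds), ratio = ratio),
    class = "peds_summary"
  )
}

#' @export
print.peds_summary <- function(x, ...) {
  cat("PEDS summary", if (!is.na(x$environment)) paste0("[", x$environment, "]"),
      "\n  n =", x$total, " mean =", sprintf("%.2f%%", x$mean),
      "\n  plants with PEDS>0 : total = 1:",
      if (is.na(x$ratio)) "undefined (no plant with PEDS > 0)" else x$ratio,
      "\n")
  print(x$bins)
  invisible(x)
}

# Deterministic per-stage seed derived from the master seed and the stage
# name, so adding a stage does not shift the randomness of the others.
stage_seed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  h <- sum(u * (seq_along(u) %% 7 + 1) * 131) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Run the full QTL-seq + linkage-mapping pipeline on simulated data
#'
#' Executes simulate -> phenotype summary -> bulks -> snp-index -> windows
#' -> null thresholds -> candidate regions -> local map -> single-QTL scan
#' -> epistasis scan, writing every intermediate artifact plus a
#' machine-readable manifest and a recovery report comparing the called
#' regions and QTL peaks against the simulator's planted truth.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created; existing files overwritten).
#' @param n_scan number of plants genotyped for the linkage arm.
#' @param high_rule,low_rule bulk eligibility predicates on PEDS.
#' @param window_bp,step_bp sliding-window size and increment.
#' @param alpha significance level for region calling.
#' @param scan_step_cM,epi_step_cM grid steps of the two scans.
#' @param lod_threshold,epi_lod_threshold peak-declaration thresholds.
#' @return Invisibly, a list with the main stage outputs and the manifest.
#' @export
run_all <- function(config, outdir,
                    n_scan = 650L,
                    high_rule = function(p) p > 90,
                    low_rule = function(p) p == 0,
                    window_bp = 1e6, step_bp = 1e4,
                    alpha = 0.05,
                    scan_step_cM = 1, epi_step_cM = 5,
                    lod_threshold = 3, epi_lod_threshold = 5) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  unlink(log_path)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- simulate ---------------------------------------------------------
  set.seed(stage_seed(config$seed, "simulate"))
  sim <- run_stage("simulate", simulate_scheme(config))
  pop <- sim$population
  peds <- vapply(pop, function(i) i$peds, numeric(1))
  write_phenotype_csv(
    data.frame(id = seq_along(peds), peds_percent = peds),
    file.path(outdir, "phenotypes.csv")
  )
  truth <- sim$truth
  jsonlite::write_json(
    list(seed = config$seed, qtl = truth$qtl, epistasis = truth$epistasis),
    file.path(outdir, "truth.json"), dataframe = "rows", digits = NA
  )
  logf("simulate", "generation %s, n = %d, PEDS>0 fraction = %.4f",
       sim$generation, length(peds), mean(peds > 0))

  # --- summarize --------------------------------------------------------
  summary <- summarize_phenotypes(peds, environment = sim$generation)
  jsonlite::write_json(
    list(environment = summary$environment, bins = as.list(summary$bins),
         total = summary$total, mean = summary$mean, ratio = summary$ratio),
    file.path(outdir, "phenotype_summary.json"), auto_unbox = TRUE, digits = NA
  )

  # --- bulks + read counts ---------------------------------------------
  set.seed(stage_seed(config$seed, "bulks"))
  bulks <- run_stage("bulks", build_bulks(pop, high_rule, low_rule,
                                          config$n_bulk))
  snps <- diagnostic_snps(config)
  counts <- run_stage("bulks", simulate_bulk_counts(
    pop, bulks$high, bulks$low, snps,
    depth_lambda = config$depth_lambda, seq_error = config$seq_error
  ))
  write_allele_counts(counts, file.path(outdir, "allele_counts.tsv"))
  logf("bulks", "high bulk n = %d, low bulk n = %d, SNPs = %d",
       length(bulks$high), length(bulks$low), nrow(counts))

  # --- snp-index --------------------------------------------------------
  si <- run_stage("snp-index", compute_snp_index(counts))
  n_drop <- sum(is.na(si$delta))
  logf("snp-index", "SNPs dropped by the 4x/32x depth filter: %d of %d",
       n_drop, nrow(si))
  utils::write.table(si, file.path(outdir, "snp_index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  win <- run_stage("snp-index", sliding_windows(si, window_bp, step_bp))
  utils::write.table(win, file.path(outdir, "windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- thresholds -------------------------------------------------------
  set.seed(stage_seed(config$seed, "thresholds"))
  curve <- run_stage("thresholds", null_delta_distribution(
    "F2", n_high = config$n_bulk, n_low = config$n_bulk
  ))
  write_threshold_tsv(curve, file.path(outdir, "thresholds.tsv"))

  # --- call-regions -----------------------------------------------------
  regions <- run_stage("call-regions",
                       call_candidate_regions(win, curve, alpha))
  write_regions_tsv(regions, file.path(outdir, "regions.tsv"))
  write_regions_bed(regions, file.path(outdir, "regions.bed"))
  logf("call-regions", "%d candidate region(s) at alpha = %g",
       nrow(regions), alpha)

  # --- marker screen (F2, as in the field protocol) ---------------------
  set.seed(stage_seed(config$seed, "screen"))
  marker_map <- local_marker_map()
  tab <- config$chromosomes
  marker_map$sim_cM <- marker_map$pos_bp /
    tab$length_bp[match(marker_map$chrom, tab$chrom)] *
    tab$length_cM[match(marker_map$chrom, tab$chrom)]
  loci <- data.frame(chrom = marker_map$chrom, pos_cM = marker_map$sim_cM)
  geno_of <- function(population, ids) {
    dos <- population_dosage(population[ids], loci)
    matrix(c("A", "H", "B")[dos + 1L], nrow = length(ids),
           dimnames = list(NULL, marker_map$marker))
  }
  lens <- config$chromosomes$length_cM
  f1 <- .zip_gametes(simulate_meiosis(founder_genome(lens, "maize")),
                     simulate_meiosis(founder_genome(lens, "teosinte")))
  f2_small <- advance_generation(new_population(list(f1), "F1"), "self",
                                 NULL, 36L, generation = "F2")
  geno_f2 <- geno_of(f2_small, seq_len(36L))
  distorted <- names(which(apply(geno_f2, 2, function(g) {
    segregation_chi2(as.numeric(table(factor(g, c("A", "H", "B")))))$p_value
  }) < 0.05))
  marker_keep <- marker_map[!marker_map$marker %in% distorted, , drop = FALSE]
  logf("screen", "%d of %d markers pass the F2 distortion screen",
       nrow(marker_keep), nrow(marker_map))

  # --- build-map --------------------------------------------------------
  set.seed(stage_seed(config$seed, "genotype"))
  scan_ids <- sort(sample(length(pop), min(n_scan, length(pop))))
  geno <- geno_of(pop, scan_ids)[, marker_keep$marker, drop = FALSE]
  write_genotype_csv(geno, scan_ids, file.path(outdir, "genotypes.csv"))
  map <- run_stage("build-map", build_local_map(
    geno, marker_keep[, c("marker", "chrom", "pos_bp")],
    alpha_distortion = 0 # screened in the F2; backcross markers are skewed
  ))
  write_map_tsv(map, file.path(outdir, "map.tsv"))
  logf("build-map", "%d markers mapped, %d uninformative in this population",
       nrow(map), length(attr(map, "dropped")))

  # --- scans ------------------------------------------------------------
  y <- cube_root_transform(peds[scan_ids])
  info <- marker_map[match(map$marker, marker_map$marker),
                     c("marker", "chrom", "pos_bp")]
  geno_kept <- geno[, map$marker, drop = FALSE]
  scan <- run_stage("scan-qtl", icim_add_scan(
    y, map, geno_kept, info, step_cM = scan_step_cM,
    lod_threshold = lod_threshold
  ))
  utils::write.table(scan$profile, file.path(outdir, "scan_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan$qtl, file.path(outdir, "qtl.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logf("scan-qtl", "%d QTL peak(s) with LOD >= %g", nrow(scan$qtl),
       lod_threshold)
  epi <- run_stage("scan-epi", icim_epi_scan(
    y, map, geno_kept, info, step_cM = epi_step_cM,
    lod_threshold = epi_lod_threshold
  ))
  utils::write.table(epi, file.path(outdir, "epistasis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logf("scan-epi", "%d epistatic pair(s) with LOD >= %g", nrow(epi),
       epi_lod_threshold)

  # --- recovery report --------------------------------------------------
  report <- .recovery_report(truth, regions, scan$qtl, map, config)
  jsonlite::write_json(report, file.path(outdir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- manifest ---------------------------------------------------------
  cfg_path <- file.path(outdir, "config.yaml")
  .write_config_yaml(config, cfg_path)
  files <- c("phenotypes.csv", "truth.json", "phenotype_summary.json",
             "allele_counts.tsv", "snp_index.tsv", "windows.tsv",
             "thresholds.tsv", "regions.tsv", "regions.bed",
             "genotypes.csv", "map.tsv", "scan_profile.tsv", "qtl.tsv",
             "epistasis.tsv", "recovery.json", "config.yaml")
  manifest <- list(
    package = "pedsqtl",
    version = as.character(utils::packageVersion("pedsqtl")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = as.list(setNames(
      unname(tools::md5sum(file.path(outdir, files))), files
    ))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary, regions = regions, qtl = scan$qtl,
                 epistasis = epi, map = map, report = report,
                 manifest = manifest, outdir = outdir))
}

# Did the QTL-seq regions and the scan peaks recover the planted QTL?
.recovery_report <- function(truth, regions, qtl_peaks, map, config,
                             tol_cM = 10) {
  tab <- config$chromosomes
  qtl <- truth$qtl
  per_qtl <- lapply(seq_len(nrow(qtl)), function(k) {
    chrom <- qtl$chrom[k]
    bp <- qtl$pos_bp[k]
    in_region <- any(regions$CHROM == chrom &
                       regions$start <= bp & bp < regions$end)
    # scan positions are on the local map scale; compare via bp anchors
    pk <- qtl_peaks[qtl_peaks$chrom == chrom, , drop = FALSE]
    found_scan <- FALSE
    if (nrow(pk) && nrow(map)) {
      mc <- map[map$chrom == chrom, , drop = FALSE]
      truth_cM <- stats::approx(mc$pos_bp, mc$pos_cM, xout = bp, rule = 2)$y
      found_scan <- any(abs(pk$pos_cM - truth_cM) <= tol_cM)
    }
    list(chrom = chrom, pos_bp = bp,
         found_qtlseq = in_region, found_scan = found_scan)
  })
  list(
    n_planted = nrow(qtl),
    n_regions_called = nrow(regions),
    n_scan_peaks = nrow(qtl_peaks),
    qtl = per_qtl
  )
}

.write_config_yaml <- function(config, path) {
  cfg <- list(
    seed = config$seed,
    n_backcrosses = config$n_backcrosses,
    n_f2 = config$n_f2, n_bcf1 = config$n_bcf1, n_final = config$n_final,
    selection_threshold = config$selection_threshold,
    n_bulk = config$n_bulk, depth_lambda = config$depth_lambda,
    seq_error = config$seq_error, snp_spacing_bp = config$snp_spacing_bp,
    chromosomes = as.list(as.data.frame(config$chromosomes)),
    qtl_model = list(
      mu = config$qtl_model$mu, sigma_e = config$qtl_model$sigma_e,
      loci = as.list(as.data.frame(config$qtl_model$loci)),
      epistasis = as.list(as.data.frame(config$qtl_model$epistasis))
    )
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML with the fields of [sim_config()]; `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  chrom <- if (!is.null(cfg$chromosomes)) {
    as.data.frame(cfg$chromosomes)
  } else {
    maize_chromosomes()
  }
  model <- if (!is.null(cfg$qtl_model)) {
    list(
      loci = as.data.frame(cfg$qtl_model$loci),
      epistasis = if (length(cfg$qtl_model$epistasis)) {
        as.data.frame(cfg$qtl_model$epistasis)
      } else {
        peds_qtl_model("major_only")$epistasis
      },
      mu = cfg$qtl_model$mu, sigma_e = cfg$qtl_model$sigma_e
    )
  } else {
    peds_qtl_model("full")
  }
  take <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  sim_config(
    seed = cfg$seed, chromosomes = chrom, qtl_model = model,
    n_backcrosses = take("n_backcrosses", 3L),
    n_f2 = take("n_f2", 2000L),
    n_bcf1 = take("n_bcf1", 100L),
    n_final = take("n_final", 6000L),
    selection_threshold = take("selection_threshold", 100),
    n_bulk = take("n_bulk", 50L),
    depth_lambda = take("depth_lambda", 19),
    seq_error = take("seq_error", 0.001),
    snp_spacing_bp = take("snp_spacing_bp", 1e5)
  )
}
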