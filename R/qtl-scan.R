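# Inclusive composite interval mapping: single-QTL additive/dominance scan
# and two-locus additive-by-additive epistasis scan, both by Haley-Knott
# regression on expected QTL genotype scores with stepwise-selected
# background markers.

#' Cube-root transformation of PEDS
#'
#' The PEDS distribution has a point mass at 0 and strong right skew; the
#' cube root reduces skewness and kurtosis while keeping 0 at 0.
#'
#' @param peds_percent PEDS values in [0, 100].
#' @return `peds_percent^(1/3)`.
#' @export
cube_root_transform <- function(peds_percent) {
  if (any(peds_percent < 0 | peds_percent > 100, na.rm = TRUE)) {
    stop("PEDS must lie in [0, 100]", call. = FALSE)
  }
  peds_percent^(1 / 3)
}

# Haldane conversions used inside the scan (no-interference model).
.haldane_r <- function(cm) (1 - exp(-2 * cm / 100)) / 2

#' Conditional F2 QTL genotype probabilities in a marker interval
#'
#' Probability of QTL genotypes (QQ = maize homozygote, Qq, qq) given the
#' genotypes of the flanking markers, under the no-interference two-locus
#' model for an F2-type population.  A missing flank is marginalized out.
#'
#' @param left,right flanking genotype codes (`"A"`, `"H"`, `"B"`, `"-"`),
#'   vectors of equal length.
#' @param r_left,r_right recombination fractions between the QTL and the
#'   left/right flanking marker, each in [0, 0.5).
#' @return Matrix (n x 3) of probabilities `P(QQ)`, `P(Qq)`, `P(qq)`.
#' @export
qtl_genotype_probs <- function(left, right, r_left, r_right) {
  if (r_left < 0 || r_left >= 0.5 || r_right < 0 || r_right >= 0.5) {
    stop("recombination fractions must lie in [0, 0.5)", call. = FALSE)
  }
  tab <- .interval_prob_table(r_left, r_right)
  codes <- c("A", "H", "B")
  li <- match(left, codes) # NA for missing
  ri <- match(right, codes)
  li[is.na(li)] <- 4L # index 4 = missing (marginalized)
  ri[is.na(ri)] <- 4L
  tab[(li - 1L) * 4L + ri, , drop = FALSE]
}

# Lookup table: rows indexed by (left genotype 1..4) x (right genotype 1..4)
# with 4 = missing, flattened as (li, ri) -> (li - 1) * 4 + ri.  Built by
# enumerating the two independent F1 gametes over the three loci L-Q-R.
.interval_prob_table <- function(r_left, r_right) {
  t12 <- function(same, r) if (same) 1 - r else r
  # gamete haplotypes: maize-allele indicators at (L, Q, R)
  haps <- expand.grid(l = 1:0, q = 1:0, r = 1:0)
  hp <- apply(haps, 1, function(h) {
    0.5 * t12(h[1] == h[2], r_left) * t12(h[2] == h[3], r_right)
  })
  # joint over two gametes -> genotype classes at each locus (# maize alleles)
  joint <- array(0, dim = c(3, 3, 3)) # [L, Q, R] classes A/H/B as 1/2/3
  for (i in seq_len(nrow(haps))) {
    for (j in seq_len(nrow(haps))) {
      gl <- 3L - (haps$l[i] + haps$l[j])
      gq <- 3L - (haps$q[i] + haps$q[j])
      gr <- 3L - (haps$r[i] + haps$r[j])
      joint[gl, gq, gr] <- joint[gl, gq, gr] + hp[i] * hp[j]
    }
  }
  tab <- matrix(0, nrow = 16, ncol = 3)
  for (li in 1:4) {
    for (ri in 1:4) {
      sl <- if (li < 4) li else 1:3
      sr <- if (ri < 4) ri else 1:3
      pq <- apply(joint[sl, , sr, drop = FALSE], 2, sum)
      tab[(li - 1) * 4 + ri, ] <- pq / sum(pq)
    }
  }
  colnames(tab) <- c("QQ", "Qq", "qq")
  tab
}

# Additive/dominance design codes from genotype codes, with mean imputation
# of missing values (used for background-marker regression only).
.marker_xz <- function(geno) {
  x <- ifelse(geno == "A", 1, ifelse(geno == "H", 0,
                                     ifelse(geno == "B", -1, NA)))
  z <- ifelse(geno == "H", 1, ifelse(geno %in% c("A", "B"), 0, NA))
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  z[is.na(z)] <- mean(z, na.rm = TRUE)
  cbind(x = x, z = z)
}

#' Stepwise selection of background markers
#'
#' Forward-backward stepwise least squares in which each marker contributes
#' an (additive, dominance) covariate pair; entry and removal use the
#' partial-F probability thresholds `p_in` and `p_out`.  Ties are broken by
#' chromosome then physical position, so the procedure is deterministic.
#'
#' @param y transformed phenotype vector.
#' @param geno genotype matrix (individuals x markers, codes A/H/B/`-`).
#' @param marker_info data.frame `marker`, `chrom`, `pos_bp` (column order
#'   of `geno`).
#' @param p_in,p_out partial-F probabilities to enter / to stay.
#' @return list with `selected` (marker names), `coef` (named matrix of
#'   additive and dominance coefficients) and the design matrices used.
#' @export
stepwise_marker_selection <- function(y, geno, marker_info,
                                      p_in = 0.01, p_out = 0.02) {
  geno <- as.matrix(geno)
  n <- length(y)
  m <- ncol(geno)
  stopifnot(nrow(geno) == n, nrow(marker_info) == m)
  if (n <= 2 * m + 1) {
    stop("n = ", n, " too small for ", m,
         " candidate markers; reduce markers or enlarge the population",
         call. = FALSE)
  }
  ord <- order(marker_info$chrom, marker_info$pos_bp)
  xz <- lapply(seq_len(m), function(j) .marker_xz(geno[, j]))
  rss_of <- function(sel) {
    X <- if (length(sel)) {
      cbind(rep(1, n), do.call(cbind, xz[sel]))
    } else {
      matrix(1, n, 1)
    }
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  partial_f_p <- function(rss_small, rss_big, df_extra, df_resid) {
    if (rss_big <= 0) return(0)
    f <- ((rss_small - rss_big) / df_extra) / (rss_big / df_resid)
    stats::pf(f, df_extra, df_resid, lower.tail = FALSE)
  }
  selected <- integer(0)
  repeat {
    changed <- FALSE
    # forward step: best candidate by partial F, ties by (chrom, bp)
    cand <- setdiff(ord, selected)
    if (length(cand)) {
      rss_cur <- rss_of(selected)
      best_p <- Inf
      best_j <- NA_integer_
      for (j in cand) {
        rss_new <- rss_of(c(selected, j))
        df_res <- n - (2 * (length(selected) + 1) + 1)
        p <- partial_f_p(rss_cur, rss_new, 2, df_res)
        if (p < best_p - 1e-12) {
          best_p <- p
          best_j <- j
        }
      }
      if (!is.na(best_j) && best_p < p_in) {
        selected <- c(selected, best_j)
        changed <- TRUE
      }
    }
    # backward step: drop any marker whose partial F probability > p_out
    if (length(selected) > 0) {
      repeat {
        rss_full <- rss_of(selected)
        df_res <- n - (2 * length(selected) + 1)
        worst_p <- -Inf
        worst_k <- NA_integer_
        for (k in seq_along(selected)) {
          p <- partial_f_p(rss_of(selected[-k]), rss_full, 2, df_res)
          if (p > worst_p) {
            worst_p <- p
            worst_k <- k
          }
        }
        if (!is.na(worst_k) && worst_p > p_out) {
          selected <- selected[-worst_k]
          changed <- TRUE
        } else {
          break
        }
      }
    }
    if (!changed) break
  }
  selected <- selected[order(match(selected, ord))]
  if (length(selected)) {
    X <- cbind(1, do.call(cbind, xz[selected]))
    fit <- stats::lm.fit(X, y)
    cf <- matrix(fit$coefficients[-1], ncol = 2, byrow = TRUE,
                 dimnames = list(marker_info$marker[selected], c("add", "dom")))
  } else {
    cf <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("add", "dom")))
  }
  list(selected = marker_info$marker[selected], index = selected,
       coef = cf, xz = xz)
}

# Phenotype adjusted by fitted background-marker effects, excluding markers
# named in `exclude`.
.adjust_phenotype <- function(y, sel, exclude) {
  keep <- setdiff(rownames(sel$coef), exclude)
  if (!length(keep)) return(y)
  adj <- y
  for (mk in keep) {
    j <- sel$index[match(mk, rownames(sel$coef))]
    adj <- adj - sel$xz[[j]] %*% sel$coef[mk, ]
  }
  as.numeric(adj)
}

# Scan grid and flanking-marker lookup for one chromosome of a genetic map.
.scan_grid <- function(map_chr, step_cM) {
  span <- range(map_chr$pos_cM)
  pos <- seq(span[1], span[2], by = step_cM)
  if (pos[length(pos)] < span[2]) pos <- c(pos, span[2])
  left <- findInterval(pos, map_chr$pos_cM, rightmost.closed = TRUE)
  left <- pmin(pmax(left, 1L), nrow(map_chr) - 1L)
  data.frame(pos_cM = pos, left = left, right = left + 1L)
}

# Expected (x*, z*) scores at a scan position for all individuals.
.expected_scores <- function(geno, map_chr, grid_row) {
  li <- grid_row$left
  ri <- grid_row$right
  r1 <- .haldane_r(grid_row$pos_cM - map_chr$pos_cM[li])
  r2 <- .haldane_r(map_chr$pos_cM[ri] - grid_row$pos_cM)
  pr <- qtl_genotype_probs(geno[, map_chr$marker[li]],
                           geno[, map_chr$marker[ri]],
                           min(r1, 0.4999), min(r2, 0.4999))
  cbind(x = pr[, "QQ"] - pr[, "qq"], z = pr[, "Qq"])
}

.fit_lod <- function(y, X) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  fit <- stats::lm.fit(cbind(1, X), y)
  rss1 <- sum(fit$residuals^2)
  list(
    lod = max(0, (n / 2) * log10(rss0 / rss1)),
    pve = 100 * (rss0 - rss1) / rss0,
    coef = fit$coefficients
  )
}

#' Single-QTL additive/dominance genome scan (ICIM-ADD)
#'
#' Walks a cM grid along each chromosome of the map.  At each position the
#' phenotype is adjusted by the fitted effects of the stepwise-selected
#' background markers except those flanking the current interval, then
#' regressed on the expected additive and dominance scores from
#' [qtl_genotype_probs()] (Haley-Knott regression).
#' LOD = (n/2) log10(RSS0/RSS1) against the intercept-only fit of the
#' adjusted phenotype; PVE, Add and Dom come from the same regression.
#'
#' @param y transformed phenotype vector.
#' @param map `genetic_map` data.frame (`marker`, `chrom`, `pos_cM`, ...).
#' @param geno genotype matrix with columns named as in the map.
#' @param marker_info data.frame `marker`, `chrom`, `pos_bp`.
#' @param step_cM scan grid step (default 1 cM).
#' @param lod_threshold LOD above which a peak is reported as a QTL.
#' @param p_in,p_out stepwise thresholds for background-marker selection.
#' @return list with `profile` (per-position LOD/PVE/Add/Dom) and `qtl`
#'   (one row per declared peak with flanking markers).
#' @export
icim_add_scan <- function(y, map, geno, marker_info, step_cM = 1,
                          lod_threshold = 3, p_in = 0.01, p_out = 0.02) {
  geno <- as.matrix(geno)
  colnames(geno) <- marker_info$marker
  sel <- stepwise_marker_selection(y, geno, marker_info, p_in, p_out)
  rows <- list()
  for (chr in unique(map$chrom)) {
    mc <- map[map$chrom == chr, , drop = FALSE]
    mc <- mc[order(mc$pos_cM), , drop = FALSE]
    if (nrow(mc) < 2) next
    grid <- .scan_grid(mc, step_cM)
    for (g in seq_len(nrow(grid))) {
      flank <- mc$marker[c(grid$left[g], grid$right[g])]
      yadj <- .adjust_phenotype(y, sel, exclude = flank)
      sc <- .expected_scores(geno, mc, grid[g, ])
      fit <- .fit_lod(yadj, sc)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr, pos_cM = grid$pos_cM[g],
        left = flank[1], right = flank[2],
        lod = fit$lod, pve = fit$pve,
        add = fit$coef[2], dom = fit$coef[3]
      )
    }
  }
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL
  list(profile = profile,
       qtl = .profile_peaks(profile, lod_threshold),
       background = sel$selected)
}

# Peaks: runs of contiguous grid positions with LOD >= threshold collapse to
# their maximum-LOD position.
.profile_peaks <- function(profile, lod_threshold) {
  out <- list()
  for (chr in unique(profile$chrom)) {
    pc <- profile[profile$chrom == chr, , drop = FALSE]
    above <- pc$lod >= lod_threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in which(runs$values)) {
      blk <- pc[starts[k]:ends[k], , drop = FALSE]
      out[[length(out) + 1]] <- blk[which.max(blk$lod), ]
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- profile[0, ]
  }
  rownames(res) <- NULL
  res
}

#' Two-locus epistasis scan (ICIM-EPI)
#'
#' For every pair of grid positions at least one step apart, fits on the
#' background-adjusted phenotype the two-locus model with main terms
#' (a1, d1, a2, d2) and the four interaction terms (aa, ad, da, dd) using
#' expected genotype scores.  LOD compares the full model against the
#' main-terms-only model; `AA` is the additive-by-additive coefficient
#' (positive = the parental-allele combination increases the phenotype) and
#' PVE is the incremental R-squared of the interaction block.  Reported
#' pairs have LOD at or above `lod_threshold` and are thinned to local
#' maxima separated by at least `min_sep_cM` on each axis.
#'
#' @inheritParams icim_add_scan
#' @param step_cM grid step (default 5 cM).
#' @param lod_threshold minimum LOD of a reported pair (default 5).
#' @param min_sep_cM pairs closer than this on both axes to an already
#'   accepted (higher-LOD) pair are suppressed.
#' @return data.frame with one row per retained pair.
#' @export
icim_epi_scan <- function(y, map, geno, marker_info, step_cM = 5,
                          lod_threshold = 5, p_in = 0.01, p_out = 0.02,
                          min_sep_cM = 20) {
  geno <- as.matrix(geno)
  colnames(geno) <- marker_info$marker
  sel <- stepwise_marker_selection(y, geno, marker_info, p_in, p_out)
  # precompute grid and scores per chromosome
  grids <- list()
  for (chr in unique(map$chrom)) {
    mc <- map[map$chrom == chr, , drop = FALSE]
    mc <- mc[order(mc$pos_cM), , drop = FALSE]
    if (nrow(mc) < 2) next
    grid <- .scan_grid(mc, step_cM)
    scores <- lapply(seq_len(nrow(grid)), function(g) {
      .expected_scores(geno, mc, grid[g, ])
    })
    grids[[as.character(chr)]] <- list(chrom = chr, map = mc, grid = grid,
                                       scores = scores)
  }
  pts <- do.call(rbind, lapply(grids, function(G) {
    data.frame(chrom = G$chrom, gi = seq_len(nrow(G$grid)),
               pos_cM = G$grid$pos_cM)
  }))
  if (is.null(pts) || nrow(pts) < 2) {
    stop("map too small for an epistasis scan", call. = FALSE)
  }
  rownames(pts) <- NULL
  rows <- list()
  np <- nrow(pts)
  for (i in seq_len(np - 1)) {
    Gi <- grids[[as.character(pts$chrom[i])]]
    for (j in (i + 1):np) {
      same <- pts$chrom[i] == pts$chrom[j]
      if (same && abs(pts$pos_cM[j] - pts$pos_cM[i]) < step_cM) next
      Gj <- grids[[as.character(pts$chrom[j])]]
      # two positions inside one flanking-marker interval are a single
      # locus as far as the data can tell; skip the degenerate pair
      if (same && Gi$grid$left[pts$gi[i]] == Gj$grid$left[pts$gi[j]]) next
      fl <- c(Gi$map$marker[c(Gi$grid$left[pts$gi[i]], Gi$grid$right[pts$gi[i]])],
              Gj$map$marker[c(Gj$grid$left[pts$gi[j]], Gj$grid$right[pts$gi[j]])])
      yadj <- .adjust_phenotype(y, sel, exclude = unique(fl))
      s1 <- Gi$scores[[pts$gi[i]]]
      s2 <- Gj$scores[[pts$gi[j]]]
      Xm <- cbind(s1, s2)
      Xi <- cbind(s1[, 1] * s2[, 1], s1[, 1] * s2[, 2],
                  s1[, 2] * s2[, 1], s1[, 2] * s2[, 2])
      n <- length(yadj)
      rss0 <- sum((yadj - mean(yadj))^2)
      fit_m <- stats::lm.fit(cbind(1, Xm), yadj)
      rss_m <- sum(fit_m$residuals^2)
      fit_f <- stats::lm.fit(cbind(1, Xm, Xi), yadj)
      rss_f <- sum(fit_f$residuals^2)
      lod <- max(0, (n / 2) * log10(rss_m / rss_f))
      if (lod < lod_threshold) next
      if (is.na(fit_f$coefficients[6])) next # interaction not identifiable
      rows[[length(rows) + 1]] <- data.frame(
        chrom1 = pts$chrom[i], pos1_cM = pts$pos_cM[i],
        interval1 = paste(fl[1], fl[2], sep = "-"),
        chrom2 = pts$chrom[j], pos2_cM = pts$pos_cM[j],
        interval2 = paste(fl[3], fl[4], sep = "-"),
        lod = lod,
        pve = 100 * (rss_m - rss_f) / rss0,
        aa = unname(fit_f$coefficients[6])
      )
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(
      chrom1 = integer(0), pos1_cM = numeric(0), interval1 = character(0),
      chrom2 = integer(0), pos2_cM = numeric(0), interval2 = character(0),
      lod = numeric(0), pve = numeric(0), aa = numeric(0)
    ))
  }
  res <- res[order(-res$lod), , drop = FALSE]
  kept <- res[0, ]
  for (k in seq_len(nrow(res))) {
    ok <- TRUE
    if (nrow(kept)) {
      clash <- kept$chrom1 == res$chrom1[k] & kept$chrom2 == res$chrom2[k] &
        abs(kept$pos1_cM - res$pos1_cM[k]) <= min_sep_cM &
        abs(kept$pos2_cM - res$pos2_cM[k]) <= min_sep_cM
      ok <- !any(clash)
    }
    if (ok) kept <- rbind(kept, res[k, ])
  }
  rownames(kept) <- NULL
  kept
}
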