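#' Unbiased expected heterozygosity of a microsatellite locus
#'
#' Gene diversity from the 2n observed allele copies with the small-sample
#' correction: H = (2n / (2n - 1)) (1 - sum p_i^2). A monomorphic locus
#' would give H = 0 and break the downstream theta ratio, so it is
#' assigned the heterozygosity obtained if exactly one of the 2n allele
#' copies differed (which simplifies to 2 / 2n) -- the convention of the
#' lnRH literature.
#'
#' @param alleles numeric vector of allele lengths: all 2n copies
#'   observed in one population (NAs dropped).
#' @return list: H, n (diploid individuals, i.e. copies/2), monomorphic.
#' @export
expected_heterozygosity <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  m <- length(alleles)                       # 2n allele copies
  if (m == 0L) return(list(H = NA_real_, n = 0, monomorphic = NA))
  if (m < 4L) abort("need >= 2 diploid individuals (4 allele copies)")
  p <- as.numeric(table(alleles)) / m
  mono <- length(p) == 1L
  if (mono) p <- c((m - 1) / m, 1 / m)       # one-copy-differs correction
  H <- (m / (m - 1)) * (1 - sum(p^2))
  list(H = H, n = m / 2, monomorphic = mono)
}

#' lnRH: log ratio of stepwise-mutation-model theta estimates
#'
#' Under the stepwise mutation model the equilibrium relationship between
#' gene diversity and theta = 4 N mu gives
#' theta_hat = 0.5 * ((1 / (1 - H))^2 - 1). lnRH = ln(theta1 / theta2)
#' compares diversity between two populations at one locus; the 0.5
#' factors cancel. Antisymmetric in its arguments.
#'
#' @param H1,H2 expected heterozygosities in (0, 1) (numerator population
#'   first; the sign of lnRH depends on this order).
#' @return lnRH value.
#' @export
lnrh <- function(H1, H2) {
  if (anyNA(c(H1, H2))) return(NA_real_)
  if (any(c(H1, H2) >= 1)) abort("H = 1: theta undefined")
  if (any(c(H1, H2) <= 0)) abort("H <= 0: theta = 0, apply the monomorphic correction first")
  th <- function(H) 0.5 * ((1 / (1 - H))^2 - 1)
  log(th(H1) / th(H2))
}

#' Standardize lnRH values against a neutral panel
#'
#' z = (lnRH - mean(neutral)) / sd(neutral) with the sample standard
#' deviation (denominator n - 1). Loci with |z| > 2 are flagged as sweep
#' candidates; the fixed cutoff is used as-is (its nominal "p < 0.01"
#' calibration is the original claim, not recomputed here). Neutral loci
#' receive z values too, for diagnostics.
#'
#' @param candidates numeric vector of candidate-locus lnRH values
#'   (optionally named).
#' @param neutral_panel numeric vector of >= 2 finite neutral-locus lnRH
#'   values.
#' @param cutoff |z| threshold (default 2).
#' @return list: z (candidates), flagged, z_neutral, mean_neutral,
#'   sd_neutral.
#' @export
standardize_lnrh <- function(candidates, neutral_panel, cutoff = 2) {
  neutral_panel <- neutral_panel[is.finite(neutral_panel)]
  if (length(neutral_panel) < 2L) abort("neutral panel needs >= 2 finite lnRH values")
  mu <- mean(neutral_panel); s <- sd(neutral_panel)
  if (s == 0) abort("neutral panel has zero lnRH variance; cannot standardize")
  z <- (candidates - mu) / s
  list(z = z, flagged = abs(z) > cutoff, z_neutral = (neutral_panel - mu) / s,
       mean_neutral = mu, sd_neutral = s)
}

#' Per-locus lnRH scan over a genotype table
#'
#' Computes expected heterozygosity per locus and population, lnRH with
#' the configured numerator population, and z-scores standardized
#' against the neutral panel.
#'
#' @param genotypes data.frame (locus, population, individual,
#'   allele1_bp, allele2_bp, panel); exactly two populations.
#' @param numerator population placed in the lnRH numerator (default the
#'   alphabetically first).
#' @param cutoff |z| flag threshold (default 2).
#' @return data.frame of class `lnrh_scan`: locus, panel, H_num, H_den,
#'   n_num, n_den, lnrh, z, flagged; attributes `numerator`,
#'   `denominator`, `mean_neutral`, `sd_neutral`.
#' @export
sweep_scan <- function(genotypes, numerator = NULL, cutoff = 2) {
  need <- c("locus", "population", "allele1_bp", "allele2_bp", "panel")
  if (!all(need %in% names(genotypes)))
    abort("genotypes must have columns: ", paste(need, collapse = ", "))
  pops <- sort(unique(genotypes$population))
  if (length(pops) != 2L) abort("exactly two populations required")
  if (is.null(numerator)) numerator <- pops[1]
  if (!numerator %in% pops) abort("numerator population not present")
  denom <- setdiff(pops, numerator)

  per_locus <- lapply(split(genotypes, genotypes$locus), function(g) {
    hs <- lapply(c(numerator, denom), function(pop) {
      gp <- g[g$population == pop, ]
      expected_heterozygosity(c(gp$allele1_bp, gp$allele2_bp))
    })
    data.frame(locus = g$locus[1], panel = g$panel[1],
               H_num = hs[[1]]$H, H_den = hs[[2]]$H,
               n_num = hs[[1]]$n, n_den = hs[[2]]$n,
               lnrh = lnrh(hs[[1]]$H, hs[[2]]$H),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_locus)
  rownames(out) <- NULL
  neutral <- out$lnrh[out$panel == "neutral"]
  st <- standardize_lnrh(out$lnrh, neutral, cutoff = cutoff)
  out$z <- st$z
  out$flagged <- st$flagged
  attr(out, "numerator") <- numerator
  attr(out, "denominator") <- denom
  attr(out, "mean_neutral") <- st$mean_neutral
  attr(out, "sd_neutral") <- st$sd_neutral
  class(out) <- c("lnrh_scan", class(out))
  out
}

#' Per-CNV-region sweep verdicts
#'
#' Aggregates the 2-4 microsatellites flanking each CNV region into one
#' verdict: "sweep-candidate" when at least one locus is flagged;
#' "low-diversity-both" when every locus has both populations'
#' heterozygosity below a low quantile of the neutral panel's H (the
#' pattern of a sweep predating the population split, or of parallel
#' sweeps); otherwise "no-signal". Inconsistent flags within a region are
#' reported verbatim in the per-locus table rather than resolved.
#'
#' @param region_map data.frame (region, locus) mapping candidate loci to
#'   CNV regions.
#' @param scan a [sweep_scan()] result.
#' @param low_quantile quantile of neutral-panel H (both populations
#'   pooled) below which a locus counts as low-diversity (default 0.05).
#' @return list: `regions` (data.frame region, n_loci, n_flagged,
#'   verdict, consistent), `loci` (per-locus rows with region), and
#'   `h_threshold`.
#' @export
sweep_report <- function(region_map, scan, low_quantile = 0.05) {
  stopifnot(all(c("region", "locus") %in% names(region_map)))
  neutralH <- c(scan$H_num[scan$panel == "neutral"],
                scan$H_den[scan$panel == "neutral"])
  h_thr <- quantile(neutralH, low_quantile, names = FALSE)
  loci <- merge(region_map, scan, by = "locus", sort = FALSE)
  missing_regions <- setdiff(region_map$region, loci$region)
  for (r in missing_regions)
    warning("region ", r, " has zero scanned loci; skipped", call. = FALSE)
  regions <- do.call(rbind, lapply(split(loci, loci$region), function(lr) {
    verdict <- if (any(lr$flagged)) "sweep-candidate"
      else if (all(lr$H_num < h_thr & lr$H_den < h_thr)) "low-diversity-both"
      else "no-signal"
    data.frame(region = lr$region[1], n_loci = nrow(lr),
               n_flagged = sum(lr$flagged), verdict = verdict,
               consistent = length(unique(lr$flagged)) == 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  list(regions = regions, loci = loci, h_threshold = h_thr)
}
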