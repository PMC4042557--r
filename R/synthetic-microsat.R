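#' Configuration for the microsatellite genotype simulator
#'
#' @param n_individuals_per_pop diploid individuals genotyped per
#'   population (default 46).
#' @param n_neutral number of neutral panel loci (default 64).
#' @param n_candidate number of candidate loci near CNV regions
#'   (default 10).
#' @param ancestral_n_alleles alleles segregating per locus in the
#'   ancestral population (default 8).
#' @param motif repeat-unit length in bp, 2 or 3 (default 2).
#' @param sweep_factor multiplier in (0, 1] applied to the diversity of
#'   swept candidate loci in the target population: 1 = neutral, small
#'   values concentrate allele frequencies on the major allele, emulating
#'   the loss of linked variation after a selective sweep (default 1).
#' @param swept_loci indices (into the candidate loci) that carry the
#'   sweep; default all candidates when `sweep_factor < 1`, none
#'   otherwise.
#' @param swept_pop population in which the sweep occurred (default
#'   "pop2").
#' @param seed integer master seed.
#' @return list of class `microsat_sim_config`.
#' @export
microsat_sim_config <- function(n_individuals_per_pop = 46, n_neutral = 64,
                                n_candidate = 10, ancestral_n_alleles = 8,
                                motif = 2, sweep_factor = 1,
                                swept_loci = NULL, swept_pop = "pop2",
                                seed = 1L) {
  if (!is_count(n_individuals_per_pop) || n_individuals_per_pop < 2)
    abort("n_individuals < 2: heterozygosity correction undefined")
  if (!motif %in% c(2, 3)) abort("motif must be 2 or 3 bp")
  if (!is.numeric(sweep_factor) || sweep_factor <= 0 || sweep_factor > 1)
    abort("sweep_factor must be in (0, 1]")
  if (is.null(swept_loci))
    swept_loci <- if (sweep_factor < 1) seq_len(n_candidate) else integer()
  if (length(swept_loci) && (any(swept_loci < 1) || any(swept_loci > n_candidate)))
    abort("swept_loci out of candidate range")
  structure(list(n_individuals_per_pop = n_individuals_per_pop,
                 n_neutral = n_neutral, n_candidate = n_candidate,
                 ancestral_n_alleles = ancestral_n_alleles,
                 motif = as.integer(motif), sweep_factor = sweep_factor,
                 swept_loci = as.integer(swept_loci), swept_pop = swept_pop,
                 seed = as.integer(seed)),
            class = "microsat_sim_config")
}

# Concentrate an allele-frequency vector on its major allele: the swept
# population keeps a fraction `f` of the ancestral spectrum and the rest
# of the mass collapses onto the most common allele.
bottleneck_freqs <- function(p, f) {
  major <- which.max(p)
  q <- f * p
  q[major] <- q[major] + (1 - f)
  q / sum(q)
}

#' Simulate diploid microsatellite genotypes for two populations
#'
#' Each locus gets a motif-spaced allele ladder (base length plus whole
#' repeat units, 5-15 repeats) and an ancestral frequency spectrum drawn
#' from a flat Dirichlet. Both populations draw genotypes from the same
#' spectrum; swept candidate loci have the target population's spectrum
#' bottlenecked by `sweep_factor` first. The sweep is phenomenological --
#' a diversity rescaling, not a coalescent with linked selection -- since
#' downstream statistics only consume genotype frequencies.
#'
#' @param config a [microsat_sim_config()].
#' @return list with `genotypes` (data.frame: locus, population,
#'   individual, allele1_bp, allele2_bp, panel) and `truth` (data.frame:
#'   locus, panel, swept).
#' @export
simulate_microsats <- function(config = microsat_sim_config()) {
  if (!inherits(config, "microsat_sim_config"))
    abort("config must be a microsat_sim_config")
  set.seed(fork_seed(config$seed, "simulate_microsats"))

  n_ind <- config$n_individuals_per_pop
  loci <- data.frame(
    locus = c(sprintf("neu%03d", seq_len(config$n_neutral)),
              sprintf("cand%03d", seq_len(config$n_candidate))),
    panel = rep(c("neutral", "candidate"),
                c(config$n_neutral, config$n_candidate)),
    stringsAsFactors = FALSE)
  loci$swept <- loci$panel == "candidate" &
    (seq_len(nrow(loci)) - config$n_neutral) %in% config$swept_loci

  rows <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    k <- config$ancestral_n_alleles
    base <- config$motif * sample(40:80, 1L)          # locus-specific base length
    ladder <- base + config$motif * (sample(5:15, 1L) + seq_len(k) - 1L)
    p <- rexp(k); p <- p / sum(p)                     # flat Dirichlet spectrum
    per_pop <- lapply(c("pop1", "pop2"), function(pop) {
      q <- p
      if (loci$swept[i] && pop == config$swept_pop)
        q <- bottleneck_freqs(p, config$sweep_factor)
      alle <- matrix(sample(ladder, 2L * n_ind, replace = TRUE, prob = q),
                     ncol = 2L)
      data.frame(locus = loci$locus[i], population = pop,
                 individual = sprintf("%s_i%02d", pop, seq_len(n_ind)),
                 allele1_bp = alle[, 1], allele2_bp = alle[, 2],
                 panel = loci$panel[i], stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_pop)
  }
  genotypes <- do.call(rbind, rows)
  rownames(genotypes) <- NULL
  list(genotypes = genotypes, truth = loci)
}
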