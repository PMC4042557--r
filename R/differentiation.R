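#' Cluster per-sample CNV calls into cross-sample loci
#'
#' Single-linkage clustering of same-sign, same-chromosome calls with at
#' least 1 bp of interval overlap (half-open coordinates). The locus
#' footprint is the union span of its member calls, and each sample
#' contributes at most one carrier flag per locus regardless of how many
#' of its calls fall in the cluster. Single linkage is the most
#' permissive matching rule consistent with reporting one footprint per
#' region.
#'
#' @param calls density-filtered calls from all samples, with
#'   `population` set.
#' @param n_pop named integer vector of samples per population; derived
#'   from the calls when omitted (samples with zero calls are then
#'   invisible, so pass it explicitly for small data).
#' @return data.frame of loci: locus_id, chrom, start, end, sign,
#'   k_pop1, k_pop2, n_pop1, n_pop2, n_carriers, member_rows (I() list of
#'   row indices into `calls`); sorted by (chrom, start).
#' @export
cluster_calls <- function(calls, n_pop = NULL) {
  if (nrow(calls) == 0L)
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(), sign = character(),
                      k_pop1 = integer(), k_pop2 = integer(),
                      n_pop1 = integer(), n_pop2 = integer(),
                      n_carriers = integer(), stringsAsFactors = FALSE))
  pops <- sort(unique(calls$population))
  if (is.null(n_pop)) {
    sm <- unique(calls[, c("sample_id", "population")])
    n_pop <- table(factor(sm$population, levels = pops))
  }
  grp <- interaction(calls$chrom, calls$sign, drop = TRUE)
  loci <- list()
  for (idx in split(seq_len(nrow(calls)), grp)) {
    o <- idx[order(calls$start[idx])]
    cur <- o[1]; cur_end <- calls$end[o[1]]
    flush <- function(members) {
      loci[[length(loci) + 1L]] <<- members
    }
    members <- o[1]
    for (i in o[-1]) {
      if (calls$start[i] < cur_end) {      # >= 1 bp overlap, half-open
        members <- c(members, i)
        cur_end <- max(cur_end, calls$end[i])
      } else {
        flush(members)
        members <- i
        cur_end <- calls$end[i]
      }
    }
    flush(members)
  }
  out <- do.call(rbind, lapply(loci, function(m) {
    carriers <- unique(calls$sample_id[m])
    carrier_pop <- calls$population[m][match(carriers, calls$sample_id[m])]
    data.frame(chrom = calls$chrom[m[1]],
               start = min(calls$start[m]), end = max(calls$end[m]),
               sign = calls$sign[m[1]],
               k_pop1 = sum(carrier_pop == pops[1]),
               k_pop2 = if (length(pops) > 1) sum(carrier_pop == pops[2]) else 0L,
               n_carriers = length(carriers), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start, out$sign), , drop = FALSE]
  out$locus_id <- sprintf("locus%04d", seq_len(nrow(out)))
  out$n_pop1 <- as.integer(n_pop[1])
  out$n_pop2 <- if (length(n_pop) > 1) as.integer(n_pop[2]) else 0L
  # match member lists to the sorted rows by (chrom, sign, start) key,
  # unique because same-sign clusters on a chromosome are disjoint
  key <- vapply(loci, function(m)
    paste(calls$chrom[m[1]], calls$sign[m[1]], min(calls$start[m])),
    character(1))
  row_key <- paste(out$chrom, out$sign, out$start)
  out$member_rows <- I(lapply(row_key, function(k) loci[[match(k, key)]]))
  rownames(out) <- NULL
  out
}

#' One-tailed hypergeometric carrier-asymmetry probability
#'
#' Probability that, distributing `K` carriers uniformly among
#' `n_major + n_minor` samples, the majority population holds at least
#' `k_major` of them:
#' sum over j >= k_major of C(n_major, j) C(n_minor, K - j) / C(n1+n2, K).
#' The test is one-tailed toward the majority population because the
#' differentiation criterion is directional by construction.
#'
#' @param k_major carriers observed in the majority population.
#' @param K total carriers across both populations.
#' @param n_major,n_minor population sample sizes (defaults 5 and 5).
#' @return the upper-tail probability.
#' @export
hypergeom_p <- function(k_major, K, n_major = 5, n_minor = 5) {
  if (!is_count(k_major) || !is_count(K) || !is_count(n_major) ||
      !is_count(n_minor))
    abort("all arguments must be non-negative integers")
  if (K > n_major + n_minor) abort("K exceeds total sample count")
  if (k_major > min(K, n_major)) abort("k_major impossible given K and n_major")
  j <- seq(k_major, min(K, n_major))
  sum(choose(n_major, j) * choose(n_minor, K - j)) /
    choose(n_major + n_minor, K)
}

#' Flag population-differentiating CNV loci
#'
#' A locus differentiates the populations when it is amplified or deleted
#' in at least `min_major` samples of one population and at most
#' `max_minor` of the other, and the one-tailed hypergeometric
#' probability of an asymmetry at least that extreme is below `alpha`.
#' Raw p-values drive the flag (no multiple-testing correction);
#' Benjamini-Hochberg adjusted values are emitted as a labeled extra
#' column for reference only.
#'
#' @param loci output of [cluster_calls()].
#' @param alpha per-locus significance level (default 0.05).
#' @param min_major minimum carriers in the majority population
#'   (default 4).
#' @param max_minor maximum carriers in the minority population
#'   (default 1).
#' @return `loci` with added columns `k_major`, `major_population`,
#'   `p_hypergeom`, `p_bh` (reference only), `is_differentiating`.
#' @export
flag_differentiating <- function(loci, alpha = 0.05, min_major = 4,
                                 max_minor = 1) {
  if (nrow(loci) == 0L) {
    loci$k_major <- integer(); loci$major_population <- character()
    loci$p_hypergeom <- numeric(); loci$p_bh <- numeric()
    loci$is_differentiating <- logical()
    return(loci)
  }
  k1 <- loci$k_pop1; k2 <- loci$k_pop2
  loci$k_major <- pmax(k1, k2)
  loci$major_population <- ifelse(k1 >= k2, "pop1", "pop2")
  n_major <- ifelse(k1 >= k2, loci$n_pop1, loci$n_pop2)
  n_minor <- ifelse(k1 >= k2, loci$n_pop2, loci$n_pop1)
  loci$p_hypergeom <- vapply(seq_len(nrow(loci)), function(i)
    hypergeom_p(loci$k_major[i], k1[i] + k2[i], n_major[i], n_minor[i]),
    numeric(1))
  loci$p_bh <- p.adjust(loci$p_hypergeom, method = "BH")
  loci$is_differentiating <- loci$k_major >= min_major &
    pmin(k1, k2) <= max_minor & loci$p_hypergeom < alpha
  loci
}
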