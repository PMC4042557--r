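# Shared fixtures and independent oracles.

# Build a probe track from a vector of log2 ratios, probes every 170 bp.
make_track <- function(ratios, sample_id = "s1", population = "pop1",
                       chrom = "chr1", region_id = "gene1", start0 = 0,
                       spacing = 170) {
  n <- length(ratios)
  st <- start0 + (seq_len(n) - 1L) * spacing
  data.frame(sample_id = rep(sample_id, n), population = rep(population, n),
             chrom = rep(chrom, n), start = st, end = st + 60L,
             region_id = rep_len(if (n) region_id else character(), n),
             log2_ratio = ratios, stringsAsFactors = FALSE)
}

# Random track over 1-3 regions with heavy-tailed ratios so runs occur.
random_track <- function(n_probes) {
  n_regions <- sample(1:3, 1)
  region <- sort(sample(seq_len(n_regions), n_probes, replace = TRUE))
  ratios <- sample(c(-1.2, -0.6, -0.3, 0, 0.3, 0.6, 1.2), n_probes,
                   replace = TRUE)
  tr <- make_track(ratios, region_id = paste0("g", region))
  tr
}

# Brute-force segmentation oracle: via cumulative exceedance counts, a
# window [i, j] is a call iff every probe exceeds +tau (or every probe
# falls below -tau) and the window is maximal. Independent of the rle
# run-tracking in call_cnvs.
oracle_call_cnvs <- function(track, params) {
  grp <- interaction(track$sample_id, track$chrom, track$region_id,
                     drop = TRUE)
  out <- list()
  for (idx in split(seq_len(nrow(track)), grp)) {
    r <- track$log2_ratio[idx]
    n <- length(r)
    if (n < params$min_probes) next
    cpos <- cumsum(r > params$tau)
    cneg <- cumsum(r < -params$tau)
    allpos <- function(i, j) (cpos[j] - if (i > 1) cpos[i - 1] else 0) == j - i + 1
    allneg <- function(i, j) (cneg[j] - if (i > 1) cneg[i - 1] else 0) == j - i + 1
    valid <- function(i, j) i >= 1 && j <= n && (allpos(i, j) || allneg(i, j))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j - i + 1 < params$min_probes) next
      if (!valid(i, j)) next
      if (valid(i - 1, j) || valid(i, j + 1)) next   # not maximal
      k <- idx[i:j]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = track$sample_id[k[1]], chrom = track$chrom[k[1]],
        start = track$start[k[1]], end = track$end[k[j - i + 1]],
        region_id = track$region_id[k[1]], n_probes = j - i + 1L,
        sign = if (r[i] > params$tau) "amplification" else "deletion",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  o <- do.call(rbind, out)
  o[order(o$sample_id, o$chrom, o$start), , drop = FALSE]
}

# Enumeration oracle for the one-tailed hypergeometric carrier test:
# enumerate every assignment of K carriers to the n1 + n2 samples and
# count those putting >= k_major in the majority population.
oracle_hypergeom <- function(k_major, K, n_major, n_minor) {
  total <- n_major + n_minor
  if (K == 0) return(if (k_major == 0) 1 else 0)
  combos <- utils::combn(total, K)
  hits <- colSums(combos <= n_major)   # samples 1..n_major are "major"
  mean(hits >= k_major)
}

# Enumeration oracle for the two-sided Fisher exact test: enumerate all
# 2x2 tables with the observed margins, computing each probability from
# factorials directly.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  table_prob <- function(x) {
    exp(lfactorial(m) + lfactorial(n) + lfactorial(k) + lfactorial(N - k) -
          lfactorial(N) - lfactorial(x) - lfactorial(m - x) -
          lfactorial(k - x) - lfactorial(n - k + x))
  }
  support <- max(0, k - n):min(k, m)
  probs <- table_prob(support)        # lfactorial is vectorized
  obs <- table_prob(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# alias for the internal summation rule so acceptance can hit it directly
fisher_two_sided_pkg <- function(a, b, c, d)
  cnvsweep:::fisher_two_sided(a, b, c, d)

# All-pairs interval intersection oracle for the overlap engine.
oracle_intersect <- function(cnvs, features, min_frac) {
  out <- list()
  for (i in seq_len(nrow(cnvs))) for (j in seq_len(nrow(features))) {
    if (cnvs$chrom[i] != features$chrom[j]) next
    ov <- min(cnvs$end[i], features$end[j]) -
      max(cnvs$start[i], features$start[j])
    if (ov <= 0) next
    if (ov / (cnvs$end[i] - cnvs$start[i]) < min_frac) next
    out[[length(out) + 1L]] <- data.frame(
      cnv_id = cnvs$cnv_id[i], feature_row = j, overlap_bp = ov,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  o <- do.call(rbind, out)
  o[order(o$cnv_id, o$feature_row), , drop = FALSE]
}

# Small two-population track set built from explicit injections.
demo_regions <- function(n = 6, len = 8000, gap = 30000) {
  data.frame(chrom = "chr1", start = (seq_len(n) - 1) * (len + gap),
             end = (seq_len(n) - 1) * (len + gap) + len,
             gene_id = sprintf("gene%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}
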