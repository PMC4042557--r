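#' Calling parameters for run-based CNV detection
#'
#' @param tau absolute log2-ratio threshold a probe must exceed
#'   (strictly) to enter a run (default 0.5).
#' @param min_probes minimum run length in probes (default 3).
#' @param max_density maximum CNV length per probe, bp/probe; calls
#'   sparser than this are removed by [density_filter()] (default 2000,
#'   i.e. at least one probe per 2 kb, boundary inclusive).
#' @return list of class `call_params`.
#' @export
call_params <- function(tau = 0.5, min_probes = 3, max_density = 2000) {
  if (!is.numeric(tau) || tau <= 0) abort("tau must be > 0")
  if (!is_count(min_probes) || min_probes < 1)
    abort("min_probes must be a positive integer")
  if (!is.numeric(max_density) || max_density <= 0)
    abort("max_density must be > 0")
  structure(list(tau = tau, min_probes = as.integer(min_probes),
                 max_density = max_density),
            class = "call_params")
}

validate_track <- function(track) {
  need <- c("sample_id", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(track)))
    abort("track must have columns: ", paste(need, collapse = ", "))
  if (!"region_id" %in% names(track)) track$region_id <- track$chrom
  if (any(!is.finite(track$log2_ratio))) abort("non-finite log2 ratios")
  grp <- interaction(track$sample_id, track$chrom, drop = TRUE)
  ok <- vapply(split(track$start, grp),
               function(s) !is.unsorted(s, strictly = TRUE), logical(1))
  if (!all(ok)) abort("track probes must be sorted with strictly increasing starts")
  track
}

#' Call CNVs from a probe-level log2-ratio track
#'
#' A CNV is a maximal run of at least `min_probes` consecutive probes
#' within one target region whose log2 ratios all exceed +tau
#' (amplification) or all fall below -tau (deletion). A sign change or a
#' sub-threshold probe terminates the run; runs never bridge
#' sub-threshold probes and never cross region boundaries, since probes
#' in distinct target regions are not consecutive on the array. Call
#' coordinates span first probe start to last probe end (half-open).
#'
#' @param track data.frame with columns `sample_id`, `population`
#'   (optional), `chrom`, `start`, `end`, `region_id` (optional; defaults
#'   to chrom), `log2_ratio`; one or more samples, sorted by (sample,
#'   chrom, start).
#' @param params a [call_params()].
#' @return data.frame of calls: sample_id, population, chrom, start, end,
#'   region_id, n_probes, sign, mean_log2, length, density; sorted by
#'   (sample_id, chrom, start). Zero rows for an empty or call-free track.
#' @export
call_cnvs <- function(track, params = call_params()) {
  if (!inherits(params, "call_params")) abort("params must be call_params")
  if (nrow(track) == 0L) return(empty_calls())
  track <- validate_track(track)
  if (!"population" %in% names(track)) track$population <- NA_character_

  grp <- interaction(track$sample_id, track$chrom, track$region_id,
                     drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(track)), grp), function(idx) {
    r <- track$log2_ratio[idx]
    state <- integer(length(r))
    state[r > params$tau] <- 1L
    state[r < -params$tau] <- -1L
    runs <- rle(state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values != 0L & runs$lengths >= params$min_probes
    if (!any(keep)) return(NULL)
    do.call(rbind, lapply(which(keep), function(k) {
      i <- idx[starts[k]:ends[k]]
      data.frame(sample_id = track$sample_id[i[1]],
                 population = track$population[i[1]],
                 chrom = track$chrom[i[1]],
                 start = track$start[i[1]],
                 end = track$end[i[length(i)]],
                 region_id = track$region_id[i[1]],
                 n_probes = length(i),
                 sign = if (runs$values[k] > 0L) "amplification" else "deletion",
                 mean_log2 = mean(track$log2_ratio[i]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty_calls())
  out$length <- out$end - out$start
  out$density <- out$length / out$n_probes
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(sample_id = character(), population = character(),
             chrom = character(), start = integer(), end = integer(),
             region_id = character(), n_probes = integer(),
             sign = character(), mean_log2 = numeric(), length = integer(),
             density = numeric(), stringsAsFactors = FALSE)
}

#' Remove probe-sparse CNV calls
#'
#' Retains calls whose probe density (length / n_probes) is at most
#' `max_density` bp per probe; the boundary is inclusive ("at least one
#' probe per 2 kb"). Order is preserved and the number removed is
#' attached as attribute `n_removed`.
#'
#' @param calls output of [call_cnvs()].
#' @param params a [call_params()].
#' @return filtered calls with attribute `n_removed`.
#' @export
density_filter <- function(calls, params = call_params()) {
  keep <- calls$density <= params$max_density
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-sample CNV summary statistics
#'
#' @param calls calls from a single sample (density-filtered).
#' @return list: n_cnvs, n_amp, n_del, size_median, size_mean,
#'   probes_median, probes_mean, densities (vector). Statistics are NA
#'   when there are no calls.
#' @export
summarize_sample <- function(calls) {
  if (nrow(calls) > 0L && length(unique(calls$sample_id)) > 1L)
    abort("summarize_sample expects calls from one sample")
  list(n_cnvs = nrow(calls),
       n_amp = sum(calls$sign == "amplification"),
       n_del = sum(calls$sign == "deletion"),
       size_median = mid_median(calls$length),
       size_mean = if (nrow(calls)) mean(calls$length) else NA_real_,
       probes_median = mid_median(calls$n_probes),
       probes_mean = if (nrow(calls)) mean(calls$n_probes) else NA_real_,
       densities = calls$density)
}

#' Compare CNV call distributions between two populations
#'
#' Computes (a) two-sample Kolmogorov-Smirnov tests (asymptotic p) on the
#' CNV size, probes-per-CNV and probe-density distributions between
#' populations; (b) a two-sided Mann-Whitney U test (normal approximation
#' with tie correction) on per-sample CNV counts; (c) a two-sided Fisher
#' exact test on the amplification/deletion x population 2x2 table; and
#' (d) a Mann-Whitney comparison of per-sample deletion counts versus
#' per-sample amplification counts (the sampling unit of the original
#' deletions-vs-amplifications comparison is ambiguous; per-sample counts
#' are used here).
#'
#' @param calls density-filtered calls carrying a `population` column
#'   with exactly two levels, and `sample_id` for per-sample counts.
#' @param samples optional data.frame (sample_id, population) so that
#'   samples with zero calls still contribute zero counts.
#' @return list of class `cnv_comparison` with elements `ks` (data.frame:
#'   metric, D, p), `mwu_counts` (U, p, per-population counts), `fisher`
#'   (table, odds ratio, p), `del_vs_amp` (U, p) and `totals`.
#' @export
compare_populations <- function(calls, samples = NULL) {
  if (is.null(samples))
    samples <- unique(calls[, c("sample_id", "population")])
  pops <- sort(unique(samples$population))
  if (length(pops) != 2L) abort("exactly two populations required")
  if (any(!table(samples$population) > 0)) abort("a population has zero samples")

  split_pop <- function(col)
    split(calls[[col]], factor(calls$population, levels = pops))
  ks <- do.call(rbind, lapply(c(size = "length", probes = "n_probes",
                                density = "density"), function(col) {
    v <- split_pop(col)
    if (length(v[[1]]) == 0L || length(v[[2]]) == 0L)
      return(data.frame(metric = col, D = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    kt <- suppressWarnings(ks.test(v[[pops[1]]], v[[pops[2]]],
                                   exact = FALSE))
    data.frame(metric = col, D = unname(kt$statistic),
               p = kt$p.value, stringsAsFactors = FALSE)
  }))
  ks$metric <- c("size", "probes", "density")
  rownames(ks) <- NULL

  counts <- table(factor(calls$sample_id, levels = samples$sample_id))
  cnt <- data.frame(sample_id = names(counts), n = as.integer(counts),
                    stringsAsFactors = FALSE)
  cnt$population <- samples$population[match(cnt$sample_id, samples$sample_id)]
  w <- suppressWarnings(
    wilcox.test(n ~ population, data = cnt, exact = FALSE, correct = FALSE))
  mwu_counts <- list(U = unname(w$statistic), p = w$p.value,
                     counts = setNames(split(cnt$n, cnt$population), pops))

  tab <- table(factor(calls$sign, levels = c("amplification", "deletion")),
               factor(calls$population, levels = pops))
  ft <- fisher.test(tab)
  fisher <- list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)

  per_sign <- lapply(c("deletion", "amplification"), function(s) {
    tb <- table(factor(calls$sample_id[calls$sign == s],
                       levels = samples$sample_id))
    as.integer(tb)
  })
  wd <- suppressWarnings(wilcox.test(per_sign[[1]], per_sign[[2]],
                                     exact = FALSE, correct = FALSE))
  del_vs_amp <- list(U = unname(wd$statistic), p = wd$p.value,
                     n_del = sum(per_sign[[1]]), n_amp = sum(per_sign[[2]]))

  totals <- list(
    n_total = nrow(calls),
    per_population = setNames(as.integer(table(
      factor(calls$population, levels = pops))), pops),
    per_sign = c(amplification = sum(calls$sign == "amplification"),
                 deletion = sum(calls$sign == "deletion")))
  structure(list(ks = ks, mwu_counts = mwu_counts, fisher = fisher,
                 del_vs_amp = del_vs_amp, totals = totals,
                 populations = pops),
            class = "cnv_comparison")
}

#' @export
print.cnv_comparison <- function(x, ...) {
  cat("CNV population comparison (", paste(x$populations, collapse = " vs "),
      ")\n", sep = "")
  cat("Totals:", x$totals$n_total, "calls (",
      paste(names(x$totals$per_population), x$totals$per_population,
            collapse = ", "), ")\n")
  cat("  amplifications:", x$totals$per_sign[["amplification"]],
      " deletions:", x$totals$per_sign[["deletion"]], "\n")
  cat("Kolmogorov-Smirnov (asymptotic):\n")
  for (i in seq_len(nrow(x$ks)))
    cat(sprintf("  %-8s D = %.4f, p = %.4g\n", x$ks$metric[i], x$ks$D[i],
                x$ks$p[i]))
  cat(sprintf("Mann-Whitney on per-sample counts: U = %g, p = %.4g\n",
              x$mwu_counts$U, x$mwu_counts$p))
  cat(sprintf("Fisher sign x population: OR = %.3f, p = %.4g\n",
              x$fisher$odds_ratio, x$fisher$p))
  cat(sprintf("Deletions vs amplifications (per-sample): U = %g, p = %.4g\n",
              x$del_vs_amp$U, x$del_vs_amp$p))
  invisible(x)
}
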