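#' Construct a target-region set for array design
#'
#' A region set describes the genic intervals an array targets. Each region
#' is extended by `flank` base pairs on both sides (clipped at zero), the
#' convention for tiling a gene body plus its regulatory neighbourhood.
#' Flank-extended regions that overlap on the same chromosome are merged,
#' concatenating their gene ids.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`,
#'   `gene_id`; 0-based half-open coordinates.
#' @param flank base pairs added up- and downstream of each region
#'   (default 10000).
#' @return data.frame of class `region_set` with columns `chrom`, `start`,
#'   `end`, `gene_id` (flank-extended, merged, sorted) and attribute
#'   `flank`.
#' @export
region_set <- function(regions, flank = 10000) {
  stopifnot(is.data.frame(regions))
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% names(regions)))
    abort("regions must have columns: ", paste(need, collapse = ", "))
  if (nrow(regions) == 0L) abort("empty region set")
  if (any(regions$start >= regions$end)) abort("region start must be < end")
  if (any(regions$start < 0)) abort("negative region coordinates")
  if (!is_count(flank)) abort("flank must be a non-negative integer")

  r <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  r$start <- pmax(0, r$start - flank)
  r$end <- r$end + flank

  out <- do.call(rbind, lapply(split(r, r$chrom), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    merged <- g[1, , drop = FALSE]
    for (i in seq_len(nrow(g))[-1]) {
      j <- nrow(merged)
      if (g$start[i] < merged$end[j]) {   # half-open overlap
        merged$end[j] <- max(merged$end[j], g$end[i])
        merged$gene_id[j] <- paste(merged$gene_id[j], g$gene_id[i], sep = ",")
      } else {
        merged <- rbind(merged, g[i, , drop = FALSE])
      }
    }
    merged
  }))
  rownames(out) <- NULL
  attr(out, "flank") <- flank
  class(out) <- c("region_set", class(out))
  out
}

#' Tile probes across a region set
#'
#' Probes are placed deterministically, left-anchored at a fixed
#' start-to-start spacing within each (flank-extended) region. Each region
#' receives `floor(length / spacing)` probes, with a minimum of one, so
#' short regions still carry a probe. Probe length is fixed at 60 bp
#' (oligonucleotide arrays), clipped at the region end.
#'
#' @param regions a [region_set()].
#' @param spacing start-to-start probe spacing in bp (default 170).
#' @return data.frame of class `probe_layout` with columns `chrom`,
#'   `start`, `end`, `region_id`, sorted by (chrom, start).
#' @export
generate_probe_layout <- function(regions, spacing = 170) {
  if (!inherits(regions, "region_set")) regions <- region_set(regions, flank = 0)
  if (nrow(regions) == 0L) abort("empty region set")
  if (!is_count(spacing) || spacing < 60) abort("spacing must be >= probe length (60 bp)")

  probe_len <- 60L
  pieces <- lapply(seq_len(nrow(regions)), function(i) {
    len <- regions$end[i] - regions$start[i]
    n <- max(1L, as.integer(len %/% spacing))
    st <- regions$start[i] + (seq_len(n) - 1L) * spacing
    data.frame(chrom = regions$chrom[i],
               start = st,
               end = pmin(st + probe_len, regions$end[i]),
               region_id = regions$gene_id[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("probe_layout", class(out))
  out
}

#' Simulation configuration for synthetic CGH tracks
#'
#' @param n_samples_per_pop samples per population (default 5).
#' @param noise_sd per-probe Gaussian noise, log2 units (default 0.15; the
#'   source arrays' empirical noise is not published, this is a stand-in).
#' @param batch_sd_inflation noise-sd multiplier applied to the samples in
#'   `batch_samples` (default 1 = off); models a batch with elevated
#'   probe-to-probe noise.
#' @param batch_samples character vector of sample ids affected by the
#'   batch inflation (default none).
#' @param cnv_size_range CNV sizes drawn log-uniformly from this range in
#'   bp (default 200 to 600000).
#' @param pop_frequencies two-column numeric matrix (pop1, pop2) of
#'   per-locus carrier probabilities; the row count sets the number of CNV
#'   loci (default 10 loci at 0.3/0.3).
#' @param copy_states candidate copy states sampled per locus; 2 is
#'   excluded by definition (default c(0, 1, 3, 4)).
#' @param zero_copy_shift finite log2 shift used for homozygous deletions,
#'   where log2(0/2) is undefined; arrays report background signal, not
#'   -Inf (default -3).
#' @param seed integer master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_pop = 5, noise_sd = 0.15,
                       batch_sd_inflation = 1, batch_samples = character(),
                       cnv_size_range = c(200, 600000),
                       pop_frequencies = matrix(0.3, nrow = 10, ncol = 2),
                       copy_states = c(0L, 1L, 3L, 4L),
                       zero_copy_shift = -3, seed = 1L) {
  if (!is_count(n_samples_per_pop) || n_samples_per_pop < 1)
    abort("n_samples_per_pop must be a positive integer")
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort("noise_sd must be > 0")
  if (batch_sd_inflation < 1) abort("batch_sd_inflation must be >= 1")
  if (length(cnv_size_range) != 2L || cnv_size_range[1] < 1 ||
      cnv_size_range[1] > cnv_size_range[2])
    abort("cnv_size_range must be an increasing pair of positive sizes")
  pop_frequencies <- as.matrix(pop_frequencies)
  if (ncol(pop_frequencies) != 2L || any(pop_frequencies < 0) ||
      any(pop_frequencies > 1))
    abort("pop_frequencies must be a two-column matrix of probabilities")
  if (any(copy_states == 2L) || any(copy_states < 0))
    abort("copy_states must be non-negative and exclude 2")
  structure(list(n_samples_per_pop = n_samples_per_pop, noise_sd = noise_sd,
                 batch_sd_inflation = batch_sd_inflation,
                 batch_samples = batch_samples,
                 cnv_size_range = cnv_size_range,
                 pop_frequencies = pop_frequencies,
                 copy_states = as.integer(copy_states),
                 zero_copy_shift = zero_copy_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

copy_state_shift <- function(copy_state, zero_copy_shift = -3) {
  ifelse(copy_state == 0L, zero_copy_shift, log2(copy_state / 2))
}

#' Simulate probe-level CGH tracks with a known CNV truth set
#'
#' Each probe's log2 ratio is the expected shift of any truth CNV covering
#' it for that sample (0 elsewhere) plus Gaussian noise. Copy states map
#' to shifts by log2(copies/2); homozygous deletions get the configured
#' finite floor shift. CNV loci are placed uniformly within regions with
#' log-uniform sizes, and carriers are drawn per population from
#' `pop_frequencies`; alternatively an explicit `truth` table is injected
#' as-is.
#'
#' @param layout a [generate_probe_layout()] result.
#' @param config a [sim_config()].
#' @param truth optional explicit truth set: data.frame with columns
#'   `sample_id`, `chrom`, `start`, `end`, `copy_state`; overrides random
#'   locus generation.
#' @return list with `tracks` (data.frame: sample_id, population, chrom,
#'   start, end, region_id, log2_ratio, sorted per sample) and `truth`
#'   (data.frame: sample_id, population, chrom, start, end, copy_state,
#'   expected_shift, locus_id).
#' @export
simulate_cgh <- function(layout, config = sim_config(), truth = NULL) {
  stopifnot(inherits(layout, "probe_layout"))
  if (!inherits(config, "sim_config")) abort("config must be a sim_config")
  set.seed(fork_seed(config$seed, "simulate_cgh"))

  pops <- c("pop1", "pop2")
  samples <- data.frame(
    sample_id = paste0(rep(pops, each = config$n_samples_per_pop), "_s",
                       rep(seq_len(config$n_samples_per_pop), 2)),
    population = rep(pops, each = config$n_samples_per_pop),
    stringsAsFactors = FALSE)

  if (is.null(truth)) {
    truth <- draw_truth_cnvs(layout, config, samples)
  } else {
    need <- c("sample_id", "chrom", "start", "end", "copy_state")
    if (!all(need %in% names(truth)))
      abort("truth must have columns: ", paste(need, collapse = ", "))
    if (!all(truth$chrom %in% layout$chrom))
      abort("injected CNV outside layout span")
    for (i in seq_len(nrow(truth))) {
      span <- layout[layout$chrom == truth$chrom[i], ]
      if (truth$end[i] <= min(span$start) || truth$start[i] >= max(span$end))
        abort("injected CNV outside layout span")
    }
    if (!"locus_id" %in% names(truth))
      truth$locus_id <- paste0("cnv", seq_len(nrow(truth)))
    if (!"population" %in% names(truth))
      truth$population <- samples$population[match(truth$sample_id,
                                                   samples$sample_id)]
  }
  truth$expected_shift <- copy_state_shift(truth$copy_state,
                                           config$zero_copy_shift)

  n_probes <- nrow(layout)
  tracks <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    mu <- numeric(n_probes)
    tr <- truth[truth$sample_id == sid, , drop = FALSE]
    for (j in seq_len(nrow(tr))) {
      hit <- layout$chrom == tr$chrom[j] &
        layout$start < tr$end[j] & layout$end > tr$start[j]
      mu[hit] <- tr$expected_shift[j]
    }
    sdev <- config$noise_sd *
      if (sid %in% config$batch_samples) config$batch_sd_inflation else 1
    tracks[[i]] <- data.frame(sample_id = sid,
                              population = samples$population[i],
                              chrom = layout$chrom,
                              start = layout$start, end = layout$end,
                              region_id = layout$region_id,
                              log2_ratio = mu + rnorm(n_probes, 0, sdev),
                              stringsAsFactors = FALSE)
  }
  tracks <- do.call(rbind, tracks)
  rownames(tracks) <- NULL
  list(tracks = tracks, truth = truth)
}

# Place CNV loci inside regions and draw per-sample carriers from the
# per-population frequencies.
draw_truth_cnvs <- function(layout, config, samples) {
  regions <- unique(layout[, c("chrom", "region_id")])
  region_span <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    p <- layout[layout$region_id == regions$region_id[i] &
                  layout$chrom == regions$chrom[i], ]
    data.frame(chrom = regions$chrom[i], region_id = regions$region_id[i],
               start = min(p$start), end = max(p$end),
               stringsAsFactors = FALSE)
  }))
  n_loci <- nrow(config$pop_frequencies)
  out <- list()
  for (l in seq_len(n_loci)) {
    reg <- region_span[sample.int(nrow(region_span), 1L), ]
    size <- round(exp(runif(1, log(config$cnv_size_range[1]),
                            log(min(config$cnv_size_range[2],
                                    reg$end - reg$start)))))
    start <- reg$start + sample.int(max(1L, reg$end - reg$start - size), 1L) - 1L
    cs <- sample(config$copy_states, 1L)
    carriers <- c(
      samples$sample_id[samples$population == "pop1"][
        rbinom(sum(samples$population == "pop1"), 1,
               config$pop_frequencies[l, 1]) == 1],
      samples$sample_id[samples$population == "pop2"][
        rbinom(sum(samples$population == "pop2"), 1,
               config$pop_frequencies[l, 2]) == 1])
    if (length(carriers) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      sample_id = carriers,
      population = samples$population[match(carriers, samples$sample_id)],
      chrom = reg$chrom, start = start, end = start + size,
      copy_state = cs, locus_id = paste0("cnv", l),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(sample_id = character(), population = character(),
                      chrom = character(), start = integer(),
                      end = integer(), copy_state = integer(),
                      locus_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Build exon/intron gene models over a region set
#'
#' For each gene (the original, un-flanked interval is not retained, so
#' models are laid over the supplied intervals): one 5'-exon, a
#' configurable number of internal exons, one 3'-exon, and introns filling
#' every gap, partitioning the gene body without overlap.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `gene_id`
#'   (gene bodies, 0-based half-open).
#' @param exons_per_gene internal exon count per gene (default 3).
#' @param exon_length length of each exon in bp (default 200).
#' @return data.frame of features: `chrom`, `start`, `end`, `gene_id`,
#'   `class` in {intron, exon, exon3, exon5}.
#' @export
make_gene_models <- function(regions, exons_per_gene = 3, exon_length = 200) {
  stopifnot(is.data.frame(regions))
  if (!is_count(exons_per_gene)) abort("exons_per_gene must be a count")
  if (!is_count(exon_length) || exon_length < 1)
    abort("exon_length must be a positive integer")
  pieces <- lapply(seq_len(nrow(regions)), function(i) {
    gstart <- regions$start[i]; gend <- regions$end[i]
    glen <- gend - gstart
    n_exons <- exons_per_gene + 2L
    if (n_exons * exon_length > glen)
      abort("total exon length exceeds gene length for gene ",
            regions$gene_id[i])
    # exon starts spread evenly; first at gene start, last flush with end
    anchors <- round(seq(gstart, gend - exon_length, length.out = n_exons))
    cls <- c("exon5", rep("exon", exons_per_gene), "exon3")
    feats <- data.frame(chrom = regions$chrom[i], start = anchors,
                        end = anchors + exon_length,
                        gene_id = regions$gene_id[i], class = cls,
                        stringsAsFactors = FALSE)
    gaps <- data.frame(chrom = regions$chrom[i],
                       start = head(feats$end, -1),
                       end = feats$start[-1],
                       gene_id = regions$gene_id[i], class = "intron",
                       stringsAsFactors = FALSE)
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
    rbind(feats, gaps)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
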