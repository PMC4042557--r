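#' Pipeline configuration
#'
#' Validates every stage parameter against its owning type's constraints
#' before any stage runs, so bad values fail fast rather than mid-run.
#'
#' @param out_dir output directory (created if absent).
#' @param probes path to a probe-track TSV; NULL to simulate.
#' @param features path to a feature BED (gene_id|class names) or GFF3;
#'   NULL to generate models alongside the simulation.
#' @param expression path to an expression-stats TSV; NULL to simulate.
#' @param genotypes path to a genotype CSV; NULL to simulate.
#' @param params a [call_params()].
#' @param alpha,min_major,max_minor differentiation parameters (defaults
#'   0.05, 4, 1).
#' @param min_frac_of_cnv overlap fraction rule (default 0.10).
#' @param numerator lnRH numerator population (default "pop1").
#' @param sim a [sim_config()] used when `probes` is NULL.
#' @param microsat_sim a [microsat_sim_config()] used when `genotypes`
#'   is NULL.
#' @param seed master seed; forked per stage.
#' @param verbose logical; stage progress to stderr.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, probes = NULL, features = NULL,
                            expression = NULL, genotypes = NULL,
                            params = call_params(), alpha = 0.05,
                            min_major = 4, max_minor = 1,
                            min_frac_of_cnv = 0.10, numerator = "pop1",
                            sim = NULL, microsat_sim = NULL, seed = 1L,
                            verbose = FALSE) {
  if (!inherits(params, "call_params")) abort("params must be call_params")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (!is_count(min_major) || !is_count(max_minor))
    abort("min_major and max_minor must be counts")
  if (min_frac_of_cnv < 0 || min_frac_of_cnv > 1)
    abort("min_frac_of_cnv must be in [0, 1]")
  for (p in c(probes, features, expression, genotypes))
    if (!file.exists(p)) abort("input file not found: ", p)
  structure(list(out_dir = out_dir, probes = probes, features = features,
                 expression = expression, genotypes = genotypes,
                 params = params, alpha = alpha, min_major = min_major,
                 max_minor = max_minor, min_frac_of_cnv = min_frac_of_cnv,
                 numerator = numerator,
                 sim = sim, microsat_sim = microsat_sim,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

stage_msg <- function(config, ...) {
  if (config$verbose) message("[cnvsweep] ", ...)
}

default_demo_regions <- function(n_regions = 20, region_len = 20000,
                                 gap = 60000) {
  data.frame(chrom = rep(c("chr1", "chr2"), length.out = n_regions),
             start = rep(seq_len(ceiling(n_regions / 2)) - 1, each = 2,
                         length.out = n_regions) * (region_len + gap),
             end = rep(seq_len(ceiling(n_regions / 2)) - 1, each = 2,
                       length.out = n_regions) * (region_len + gap) +
               region_len,
             gene_id = sprintf("gene%03d", seq_len(n_regions)),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (for any input not supplied) -> call-cnvs ->
#' diff-loci -> overlap -> expr-assoc -> sweep-scan, writing each stage's
#' outputs under `config$out_dir` and returning a manifest with per-file
#' MD5 checksums. Identical config, inputs and seed reproduce identical
#' stage outputs. A stage failure aborts with the stage name; files
#' already written are retained.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_manifest`: version, config, files (path ->
#'   md5), timings (seconds per stage), results (in-memory stage
#'   outputs).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    abort("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(); timings <- c()
  run_stage <- function(name, fn) {
    stage_msg(config, "stage ", name)
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(fn(), error = function(e)
      abort("stage '", name, "' failed: ", conditionMessage(e)))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    r
  }
  fpath <- function(...) file.path(config$out_dir, ...)

  sim_cfg <- config$sim %||% sim_config(seed = config$seed)
  features <- NULL

  if (is.null(config$probes)) {
    simres <- run_stage("simulate", function() {
      regions <- default_demo_regions()
      rs <- region_set(regions, flank = 10000)
      layout <- generate_probe_layout(rs)
      out <- simulate_cgh(layout, sim_cfg)
      features <<- make_gene_models(regions)
      write_probe_tracks(out$tracks, fpath("probes.tsv"))
      write_bed(data.frame(chrom = out$truth$chrom, start = out$truth$start,
                           end = out$truth$end,
                           name = paste(out$truth$sample_id,
                                        out$truth$copy_state, sep = ":"),
                           stringsAsFactors = FALSE), fpath("truth.bed"))
      write_features_bed(features, fpath("features.bed"))
      out
    })
    tracks <- simres$tracks
  } else {
    tracks <- run_stage("read-probes", function()
      read_probe_tracks(config$probes))
  }
  if (is.null(features)) {
    features <- if (is.null(config$features)) {
      run_stage("simulate-features", function() {
        f <- make_gene_models(default_demo_regions())
        write_features_bed(f, fpath("features.bed"))
        f
      })
    } else if (grepl("\\.gff3?$", config$features)) {
      run_stage("read-features", function()
        read_gff3_features(config$features))
    } else {
      run_stage("read-features", function()
        read_features_bed(config$features))
    }
  }

  calls <- run_stage("call-cnvs", function() {
    cl <- call_cnvs(tracks, config$params)
    cl <- density_filter(cl, config$params)
    write_calls(cl, fpath("calls.bed"), fpath("calls.tsv"))
    cl
  })
  results$calls <- calls

  comparison <- run_stage("compare-populations", function() {
    samples <- unique(tracks[, c("sample_id", "population")])
    cp <- compare_populations(calls, samples)
    kv <- data.frame(
      key = c(paste0("ks_", cp$ks$metric, "_D"),
              paste0("ks_", cp$ks$metric, "_p"),
              "mwu_counts_U", "mwu_counts_p", "fisher_or", "fisher_p",
              "del_vs_amp_U", "del_vs_amp_p", "n_total"),
      value = c(cp$ks$D, cp$ks$p, cp$mwu_counts$U, cp$mwu_counts$p,
                cp$fisher$odds_ratio, cp$fisher$p, cp$del_vs_amp$U,
                cp$del_vs_amp$p, cp$totals$n_total))
    write.table(kv, fpath("comparison.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cp
  })
  results$comparison <- comparison

  loci <- run_stage("diff-loci", function() {
    samples <- unique(tracks[, c("sample_id", "population")])
    n_pop <- table(samples$population)
    lc <- cluster_calls(calls, n_pop = n_pop)
    lc <- flag_differentiating(lc, alpha = config$alpha,
                               min_major = config$min_major,
                               max_minor = config$max_minor)
    out <- lc[, c("chrom", "start", "end", "locus_id", "sign", "k_pop1",
                  "k_pop2", "p_hypergeom", "p_bh", "is_differentiating")]
    write.table(out, fpath("loci.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    lc
  })
  results$loci <- loci

  overlaps <- run_stage("overlap", function() {
    cn <- calls
    cn$cnv_id <- sprintf("%s_%05d", cn$sample_id, seq_len(nrow(cn)))
    rec <- intersect_cnv_features(cn, features,
                                  min_frac_of_cnv = config$min_frac_of_cnv)
    write.table(rec, fpath("overlaps.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(records = rec, summary = summarize_overlaps(rec))
  })
  results$overlaps <- overlaps

  expr <- run_stage("expr-assoc", function() {
    stats <- if (is.null(config$expression)) {
      genes <- unique(features$gene_id)
      carrier <- genes %in% overlaps$records$gene_id
      simulate_expression_stats(
        data.frame(gene_id = genes, cnv_carrier = carrier,
                   stringsAsFactors = FALSE),
        coupling = 0, seed = fork_seed(config$seed, "expr"))
    } else read_expression_stats(config$expression)
    sizes <- tapply(calls$length, calls$region_id, max)
    cnv_sizes <- setNames(as.numeric(sizes), names(sizes))
    combos <- unique(stats[, c("tissue", "platform")])
    assoc <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      ct <- correlate_cnv_expression(cnv_sizes, stats, combos$tissue[i],
                                     combos$platform[i])
      data.frame(tissue = combos$tissue[i], platform = combos$platform[i],
                 rho = ct$rho, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
    }))
    write.table(assoc, fpath("expr_assoc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(stats = stats, assoc = assoc)
  })
  results$expression <- expr

  sweep <- run_stage("sweep-scan", function() {
    if (is.null(config$genotypes)) {
      ms_cfg <- config$microsat_sim %||%
        microsat_sim_config(seed = config$seed)
      gt <- simulate_microsats(ms_cfg)$genotypes
      write_genotypes(gt, fpath("genotypes.csv"))
    } else {
      if (!file.exists(config$genotypes))
        abort("missing genotype file: ", config$genotypes)
      gt <- read_genotypes(config$genotypes)
    }
    sc <- sweep_scan(gt, numerator = config$numerator)
    write.table(as.data.frame(sc), fpath("sweep_scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sc
  })
  results$sweep <- sweep

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- structure(
    list(version = as.character(utils::packageVersion("cnvsweep")),
         config = config,
         files = setNames(as.character(tools::md5sum(files)),
                          basename(files)),
         timings = unlist(timings), results = results),
    class = "run_manifest")
  manifest
}
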