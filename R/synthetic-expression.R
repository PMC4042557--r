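#' Simulate per-gene expression differential statistics
#'
#' Produces a gene x tissue x platform table of t statistics and p-values
#' mimicking a two-platform, three-tissue differential-expression screen.
#' Non-DE genes draw t from the central null (p-values uniform); DE genes
#' get a mean shift of `effect_size`. With `coupling > 0`, that fraction
#' of CNV-carrier genes is forced DE with a shift whose sign matches the
#' copy change (amplification up, deletion down) with probability
#' `sign_match_prob`.
#'
#' @param genes data.frame with columns `gene_id`, `cnv_carrier`
#'   (logical) and optionally `cnv_sign` ("amplification"/"deletion") and
#'   `de` (logical; default 20% DE among non-carriers).
#' @param coupling fraction of CNV-carrier genes with a true expression
#'   shift, in \[0, 1\].
#' @param effect_size mean |t| shift for DE genes (default 4).
#' @param sign_match_prob probability the coupled shift matches the copy
#'   change direction (default 1).
#' @param tissues,platforms factor levels of the design.
#' @param seed integer seed.
#' @return data.frame: gene_id, tissue, platform, p_value, t_statistic,
#'   status in {DE, invariant}.
#' @export
simulate_expression_stats <- function(genes, coupling = 0, effect_size = 4,
                                      sign_match_prob = 1,
                                      tissues = c("brain", "liver", "testis"),
                                      platforms = c("A", "B"), seed = 1L) {
  stopifnot(is.data.frame(genes), "gene_id" %in% names(genes))
  if (!is.numeric(coupling) || coupling < 0 || coupling > 1)
    abort("coupling must be in [0, 1]")
  if (!"cnv_carrier" %in% names(genes)) genes$cnv_carrier <- FALSE
  set.seed(fork_seed(seed, "simulate_expression"))

  n <- nrow(genes)
  if (!"de" %in% names(genes)) genes$de <- runif(n) < 0.2
  if (!"cnv_sign" %in% names(genes)) genes$cnv_sign <- "amplification"

  coupled <- genes$cnv_carrier & runif(n) < coupling
  is_de <- genes$de | coupled
  # per-gene direction: coupled genes follow the copy change, the rest coin-flip
  dir_gene <- ifelse(runif(n) < 0.5, 1, -1)
  cnv_dir <- ifelse(genes$cnv_sign == "deletion", -1, 1)
  match_sign <- runif(n) < sign_match_prob
  dir_gene[coupled] <- ifelse(match_sign[coupled], cnv_dir[coupled],
                              -cnv_dir[coupled])

  grid <- expand.grid(tissue = tissues, platform = platforms,
                      idx = seq_len(n), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  mu <- ifelse(is_de[grid$idx], effect_size * dir_gene[grid$idx], 0)
  t_stat <- rnorm(nrow(grid), mean = mu, sd = 1)
  out <- data.frame(gene_id = genes$gene_id[grid$idx],
                    tissue = grid$tissue, platform = grid$platform,
                    p_value = 2 * pnorm(-abs(t_stat)),
                    t_statistic = t_stat,
                    status = ifelse(is_de[grid$idx], "DE", "invariant"),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$tissue, out$platform), , drop = FALSE]
}
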