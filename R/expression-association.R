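#' Spearman correlation between CNV size and expression differentiation
#'
#' Correlates per-gene CNV size with an expression statistic (p-value by
#' default) within one tissue x platform stratum. Genes without a CNV
#' enter with size 0 so the correlation runs over the whole tested gene
#' panel; set `carriers_only = TRUE` to restrict to CNV genes.
#'
#' @param cnv_sizes named numeric vector of CNV sizes (bp) per gene_id;
#'   genes absent from it get size 0.
#' @param stats expression table (gene_id, tissue, platform, p_value,
#'   t_statistic, status).
#' @param tissue,platform stratum selectors.
#' @param statistic which expression column to rank against: "p_value"
#'   (default) or abs_t.
#' @param carriers_only drop genes with size 0 (default FALSE).
#' @return list: rho, p (two-sided, t approximation), n, undefined
#'   (TRUE when a vector is constant and the correlation does not exist).
#' @export
correlate_cnv_expression <- function(cnv_sizes, stats, tissue, platform,
                                     statistic = c("p_value", "abs_t"),
                                     carriers_only = FALSE) {
  statistic <- match.arg(statistic)
  s <- stats[stats$tissue == tissue & stats$platform == platform, ,
             drop = FALSE]
  if (nrow(s) == 0L) abort("no expression rows for that tissue/platform")
  size <- unname(cnv_sizes[s$gene_id])
  size[is.na(size)] <- 0
  y <- if (statistic == "p_value") s$p_value else abs(s$t_statistic)
  if (carriers_only) {
    keep <- size > 0
    size <- size[keep]; y <- y[keep]
  }
  if (length(size) < 3L) abort("need at least 3 genes with data")
  if (length(unique(size)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = length(size),
                undefined = TRUE))
  ct <- suppressWarnings(cor.test(size, y, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(size),
       undefined = FALSE)
}

# Two-sided Fisher exact p for a 2x2 table by the minimum-likelihood
# summation rule: sum the hypergeometric probabilities of all tables with
# the observed margins whose probability does not exceed the observed
# table's (within a relative tolerance, as in stats::fisher.test).
fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' CNV enrichment among differentially expressed vs invariant genes
#'
#' Builds the 2x2 table of CNV-carrier counts within the DE and invariant
#' gene sets and applies a two-sided Fisher exact test (minimum-likelihood
#' summation). The odds ratio is the sample cross-product ratio, not the
#' conditional MLE.
#'
#' @param n_cnv_in_de CNV-carrier genes among the DE set.
#' @param n_de size of the DE gene set.
#' @param n_cnv_in_inv CNV-carrier genes among the invariant set.
#' @param n_inv size of the invariant gene set.
#' @return list: table (2x2 matrix), odds_ratio, p.
#' @export
de_enrichment <- function(n_cnv_in_de, n_de, n_cnv_in_inv, n_inv) {
  args <- c(n_cnv_in_de, n_de, n_cnv_in_inv, n_inv)
  if (any(!vapply(args, is_count, logical(1))))
    abort("counts must be non-negative integers")
  if (n_cnv_in_de > n_de || n_cnv_in_inv > n_inv)
    abort("CNV count exceeds its group size")
  tab <- matrix(c(n_cnv_in_de, n_de - n_cnv_in_de,
                  n_cnv_in_inv, n_inv - n_cnv_in_inv),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("DE", "invariant"), c("cnv", "no_cnv")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- fisher_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  list(table = tab, odds_ratio = or, p = p)
}

# Exact two-sided binomial test with success probability 1/2:
# p = 2 * min(P(X <= k), P(X >= k)), capped at 1.
binom_two_sided <- function(k, n) {
  if (n == 0L) return(NA_real_)
  min(1, 2 * min(pbinom(k, n, 0.5), 1 - pbinom(k - 1, n, 0.5)))
}

#' Direction concordance between differentiating CNVs and expression
#'
#' Classifies each differentiating locus by whether the expression change
#' of its gene runs in the direction copy dosage predicts (amplification
#' up / deletion down = "expected", the converse = "opposite", no DE gene
#' = "no_change", conflicting directions across tissues =
#' "opposing_tissues"), then tests expected vs opposite counts with an
#' exact two-sided binomial test at success probability 1/2.
#'
#' A locus overlapping several genes takes the gene with the smallest
#' expression p-value. The gene's direction is the sign of its t
#' statistic among DE rows; DE rows of both signs across tissues give
#' "opposing_tissues".
#'
#' @param locus_genes data.frame mapping loci to genes: `locus_id`,
#'   `gene_id`, `cnv_sign`.
#' @param stats expression table (gene_id, tissue, platform, p_value,
#'   t_statistic, status).
#' @return list of class `concordance_result`: `records` (per-locus
#'   classification), `counts` (named: expected, opposite, no_change,
#'   opposing_tissues), `n_total`, `p_binomial`.
#' @export
direction_concordance <- function(locus_genes, stats) {
  need <- c("locus_id", "gene_id", "cnv_sign")
  if (!all(need %in% names(locus_genes)))
    abort("locus_genes must have columns: ", paste(need, collapse = ", "))
  recs <- lapply(split(locus_genes, locus_genes$locus_id), function(lg) {
    s <- stats[stats$gene_id %in% lg$gene_id, , drop = FALSE]
    if (nrow(s) == 0L)
      return(data.frame(locus_id = lg$locus_id[1], gene_id = NA_character_,
                        direction = "none", category = "no_change",
                        stringsAsFactors = FALSE))
    best_gene <- s$gene_id[which.min(s$p_value)]
    sg <- s[s$gene_id == best_gene & s$status == "DE", , drop = FALSE]
    sign_cnv <- lg$cnv_sign[match(best_gene, lg$gene_id)]
    if (is.na(sign_cnv)) sign_cnv <- lg$cnv_sign[1]
    if (nrow(sg) == 0L) {
      dirn <- "none"; cat_ <- "no_change"
    } else {
      dirs <- unique(sign(sg$t_statistic))
      if (length(dirs) > 1L) {
        dirn <- "mixed"; cat_ <- "opposing_tissues"
      } else {
        dirn <- if (dirs > 0) "up" else "down"
        expected <- (sign_cnv == "amplification" && dirn == "up") ||
          (sign_cnv == "deletion" && dirn == "down")
        cat_ <- if (expected) "expected" else "opposite"
      }
    }
    data.frame(locus_id = lg$locus_id[1], gene_id = best_gene,
               direction = dirn, category = cat_, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  concordance_test(table(factor(records$category,
                                levels = c("expected", "opposite",
                                           "no_change", "opposing_tissues"))),
                   records = records)
}

#' Binomial concordance test on pre-tabulated category counts
#'
#' @param counts named vector or table with entries `expected`,
#'   `opposite` and optionally `no_change`, `opposing_tissues`.
#' @param records optional per-locus classification to carry through.
#' @return list of class `concordance_result`; see
#'   [direction_concordance()].
#' @export
concordance_test <- function(counts, records = NULL) {
  counts <- as.table(counts)
  lv <- c("expected", "opposite", "no_change", "opposing_tissues")
  full <- setNames(integer(4), lv)
  full[names(counts)[names(counts) %in% lv]] <-
    as.integer(counts[names(counts) %in% lv])
  n <- full[["expected"]] + full[["opposite"]]
  structure(list(records = records, counts = full,
                 n_total = sum(full),
                 p_binomial = binom_two_sided(full[["expected"]], n)),
            class = "concordance_result")
}
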