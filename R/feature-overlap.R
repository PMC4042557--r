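#' Intersect CNV calls with gene features under a fraction-of-CNV rule
#'
#' Emits one record per (CNV, feature) pair whose interval intersection
#' covers at least `min_frac_of_cnv` of the CNV's length. All coordinates
#' are 0-based half-open; overlap is strand-agnostic (CGH calls are
#' unstranded). Overlap detection uses IRanges; fractions are computed
#' from the raw coordinates.
#'
#' @param cnvs data.frame with `chrom`, `start`, `end` and a unique id
#'   column `cnv_id` (created from row numbers when absent).
#' @param features data.frame with `chrom`, `start`, `end`, `gene_id`,
#'   `class` in {intron, exon, exon3, exon5}.
#' @param min_frac_of_cnv minimum overlap as a fraction of CNV length
#'   (default 0.10).
#' @return data.frame of records: cnv_id, feature_row, chrom,
#'   feature_start, feature_end, gene_id, class, overlap_bp,
#'   fraction_of_cnv, fraction_of_feature.
#' @export
intersect_cnv_features <- function(cnvs, features, min_frac_of_cnv = 0.10) {
  if (!is.numeric(min_frac_of_cnv) || min_frac_of_cnv < 0 ||
      min_frac_of_cnv > 1)
    abort("min_frac_of_cnv must be in [0, 1]")
  if (nrow(cnvs) && any(cnvs$start >= cnvs$end))
    abort("mixed coordinate conventions: CNV with start >= end")
  if (nrow(features) && any(features$start >= features$end))
    abort("mixed coordinate conventions: feature with start >= end")
  if (!"cnv_id" %in% names(cnvs))
    cnvs$cnv_id <- sprintf("cnv%05d", seq_len(nrow(cnvs)))
  empty <- data.frame(cnv_id = character(), feature_row = integer(),
                      chrom = character(), feature_start = integer(),
                      feature_end = integer(), gene_id = character(),
                      class = character(), overlap_bp = integer(),
                      fraction_of_cnv = numeric(),
                      fraction_of_feature = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(cnvs) == 0L || nrow(features) == 0L) return(empty)

  pieces <- lapply(intersect(unique(cnvs$chrom), unique(features$chrom)),
                   function(ch) {
    ci <- which(cnvs$chrom == ch); fi <- which(features$chrom == ch)
    q <- IRanges::IRanges(cnvs$start[ci] + 1L, cnvs$end[ci])
    s <- IRanges::IRanges(features$start[fi] + 1L, features$end[fi])
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0L) return(NULL)
    a <- ci[S4Vectors::queryHits(hits)]
    b <- fi[S4Vectors::subjectHits(hits)]
    ov <- pmin(cnvs$end[a], features$end[b]) -
      pmax(cnvs$start[a], features$start[b])
    data.frame(cnv_id = cnvs$cnv_id[a], feature_row = b,
               chrom = ch,
               feature_start = features$start[b],
               feature_end = features$end[b],
               gene_id = features$gene_id[b],
               class = features$class[b],
               overlap_bp = ov,
               fraction_of_cnv = ov / (cnvs$end[a] - cnvs$start[a]),
               fraction_of_feature = ov /
                 (features$end[b] - features$start[b]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty)
  out <- out[out$fraction_of_cnv >= min_frac_of_cnv, , drop = FALSE]
  out <- out[order(out$chrom, out$feature_start, out$cnv_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize feature-overlap records
#'
#' An element is a distinct feature hit by at least one record; element
#' counts deduplicate features so a feature hit by several CNVs counts
#' once, while one CNV hitting several features contributes each of them.
#' The per-class median overlap fraction is taken over elements, using
#' each element's deepest (maximum) fraction_of_feature across the CNVs
#' that hit it.
#'
#' @param records output of [intersect_cnv_features()].
#' @return list: `n_elements` (named by class), `shares` (fractions
#'   summing to 1), `n_genes`, `median_fraction_of_feature` (named by
#'   class), `n_records`.
#' @export
summarize_overlaps <- function(records) {
  classes <- c("intron", "exon", "exon3", "exon5")
  if (nrow(records) == 0L)
    return(list(n_elements = setNames(integer(4), classes),
                shares = setNames(rep(NA_real_, 4), classes),
                n_genes = 0L,
                median_fraction_of_feature = setNames(rep(NA_real_, 4),
                                                      classes),
                n_records = 0L))
  el <- records[!duplicated(records$feature_row), , drop = FALSE]
  depth <- tapply(records$fraction_of_feature, records$feature_row, max)
  el$max_frac <- as.numeric(depth[as.character(el$feature_row)])
  n_el <- table(factor(el$class, levels = classes))
  med <- vapply(classes, function(cl) {
    v <- el$max_frac[el$class == cl]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  list(n_elements = setNames(as.integer(n_el), classes),
       shares = setNames(as.numeric(n_el) / sum(n_el), classes),
       n_genes = length(unique(records$gene_id)),
       median_fraction_of_feature = med,
       n_records = nrow(records))
}
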