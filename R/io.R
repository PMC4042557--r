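#' Read a BED file
#'
#' BED is 0-based half-open; no coordinate conversion is applied.
#' Malformed lines are reported with their line numbers.
#'
#' @param path file path.
#' @return data.frame: chrom, start, end and, when present, name, score,
#'   strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 3L)
  if (length(bad)) abort("BED line ", bad[1], ": fewer than 3 columns")
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort("BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad)) abort("BED line ", bad[1], ": start >= end")
  out <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                    start = start, end = end, stringsAsFactors = FALSE)
  if (all(ncol >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(ncol >= 5L))
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (all(ncol >= 6L)) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Write intervals as BED
#'
#' @param records data.frame with chrom, start, end and optionally name,
#'   score, strand (missing optional columns are filled with ".", 0, ".").
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  if (any(records$start >= records$end)) abort("start >= end in BED record")
  out <- data.frame(chrom = records$chrom, start = records$start,
                    end = records$end,
                    name = records$name %||% ".",
                    score = records$score %||% 0,
                    strand = records$strand %||% ".",
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# records$name may be NULL when records is a data.frame; `%||%` handles it

#' Read gene features from GFF3
#'
#' Coordinates are converted from GFF3's 1-based fully-closed convention
#' to the package's 0-based half-open convention. Feature types are
#' mapped intron -> intron, exon -> exon, three_prime_UTR -> exon3,
#' five_prime_UTR -> exon5; other types are skipped and counted.
#'
#' @param path file path.
#' @return data.frame: chrom, start, end, gene_id, class; attribute
#'   `n_skipped` counts unmapped feature types.
#' @export
read_gff3_features <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad)) abort("GFF3 line ", lineno[bad[1]], ": fewer than 9 columns")
  type <- vapply(fields, `[[`, "", 3L)
  map <- c(intron = "intron", exon = "exon",
           three_prime_UTR = "exon3", five_prime_UTR = "exon5")
  cls <- unname(map[type])
  skipped <- sum(is.na(cls))
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort("GFF3 line ", lineno[bad[1]], ": non-numeric coordinates")
  attrs <- vapply(fields, `[[`, "", 9L)
  gene <- sub(".*(?:gene_id|Parent|ID)=([^;]+).*", "\\1", attrs, perl = TRUE)
  out <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                    start = start - 1L, end = end,   # to 0-based half-open
                    gene_id = gene, class = cls,
                    stringsAsFactors = FALSE)[!is.na(cls), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Read gene features from BED
#'
#' Expects the feature class encoded in the name column as
#' `gene_id|class`.
#'
#' @param path file path.
#' @return data.frame: chrom, start, end, gene_id, class.
#' @export
read_features_bed <- function(path) {
  b <- read_bed(path)
  if (!"name" %in% names(b)) abort("feature BED needs a name column (gene|class)")
  parts <- strsplit(b$name, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) abort("feature BED name must be gene_id|class")
  data.frame(chrom = b$chrom, start = b$start, end = b$end,
             gene_id = vapply(parts, `[[`, "", 1L),
             class = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE)
}

#' Write gene features as BED (name = gene_id|class)
#' @param features data.frame with chrom, start, end, gene_id, class.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(features, path) {
  write_bed(data.frame(chrom = features$chrom, start = features$start,
                       end = features$end,
                       name = paste(features$gene_id, features$class,
                                    sep = "|"),
                       stringsAsFactors = FALSE), path)
}

#' Read / write probe tracks as tab-delimited text
#'
#' Columns: sample_id, population, chrom, start, end, region_id,
#' log2_ratio, with a one-line header.
#'
#' @param path file path.
#' @return data.frame of probes.
#' @export
read_probe_tracks <- function(path) {
  tr <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(tr)))
    abort("probe track file must have columns: ",
          paste(need, collapse = ", "))
  tr
}

#' @rdname read_probe_tracks
#' @param tracks probe-track data.frame.
#' @export
write_probe_tracks <- function(tracks, path) {
  write.table(tracks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write microsatellite genotypes as CSV
#'
#' Columns: locus, population, individual, allele1_bp, allele2_bp, panel.
#'
#' @param path file path.
#' @return genotype data.frame.
#' @export
read_genotypes <- function(path) {
  g <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("locus", "population", "individual", "allele1_bp", "allele2_bp")
  if (!all(need %in% names(g)))
    abort("genotype file must have columns: ", paste(need, collapse = ", "))
  if (!"panel" %in% names(g)) g$panel <- "candidate"
  if (any(g$allele1_bp <= 0 | g$allele2_bp <= 0, na.rm = TRUE))
    abort("allele lengths must be positive")
  g
}

#' @rdname read_genotypes
#' @param genotypes genotype data.frame.
#' @export
write_genotypes <- function(genotypes, path) {
  write.table(genotypes, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read expression statistics from TSV
#'
#' Columns: gene_id, tissue, platform, p_value, t_statistic, status.
#'
#' @param path file path.
#' @return expression data.frame.
#' @export
read_expression_stats <- function(path) {
  s <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "platform", "p_value", "t_statistic",
            "status")
  if (!all(need %in% names(s)))
    abort("expression file must have columns: ", paste(need, collapse = ", "))
  if (any(s$p_value < 0 | s$p_value > 1, na.rm = TRUE))
    abort("p_value outside [0, 1]")
  s
}

#' @rdname read_expression_stats
#' @param stats expression data.frame.
#' @export
write_expression_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CNV calls as BED6 plus an extended TSV
#'
#' The BED name is `sample:sign`, score is the probe count. The extended
#' TSV carries every call column.
#'
#' @param calls calls data.frame from [call_cnvs()].
#' @param bed_path,tsv_path output paths (either may be NULL to skip).
#' @return invisibly, a list of the paths written.
#' @export
write_calls <- function(calls, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    write_bed(data.frame(chrom = calls$chrom, start = calls$start,
                         end = calls$end,
                         name = paste(calls$sample_id, calls$sign, sep = ":"),
                         score = calls$n_probes, strand = ".",
                         stringsAsFactors = FALSE), bed_path)
  }
  if (!is.null(tsv_path))
    write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(bed = bed_path, tsv = tsv_path))
}

#' Read a simulation / pipeline configuration file
#'
#' Debian-control-style `key: value` text; keys follow the configuration
#' constructors' argument names. Numeric-looking values are converted.
#'
#' @param path file path.
#' @return named list of values.
#' @export
read_config <- function(path) {
  dcf <- read.dcf(path)
  vals <- as.list(dcf[1, ])
  lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    if (!anyNA(num)) num else v
  })
}
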