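#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rexp runif rbinom pbinom pnorm dhyper median sd
#'   ks.test wilcox.test fisher.test cor.test p.adjust quantile setNames
#' @importFrom utils read.table write.table head tail
NULL

# fail with a consistent prefix so callers can grep stage errors
abort <- function(..., call. = FALSE) stop(..., call. = call.)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0

# Fork a reproducible per-stage seed from the master seed. Kept below
# 2^31 so it is always a valid R integer.
fork_seed <- function(seed, stage) {
  stopifnot(is_count(seed))
  offsets <- c(simulate_cgh = 11L, simulate_microsats = 23L,
               simulate_expression = 37L, pipeline = 53L)
  off <- unname(offsets[stage])
  if (is.na(off)) off <- sum(utf8ToInt(stage)) %% 1000L
  as.integer((seed * 7919 + off) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# midpoint-of-two median; base median already does this for numeric
mid_median <- function(x) if (length(x) == 0L) NA_real_ else median(x)
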