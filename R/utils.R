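#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom stats rbinom rbeta rnbinom rnorm runif setNames wilcox.test
#' @importFrom utils read.table write.table
NULL

## Composite key used everywhere a canonical variant acts as a set element.
canonical_key <- function(chrom, start, end, ref, alt) {
  paste(chrom, start, end, ref, alt, sep = ":")
}

vb_warn <- function(...) warning(sprintf(...), call. = FALSE)

vb_stop <- function(...) stop(sprintf(...), call. = FALSE)

is_dna <- function(x) grepl("^[ACGTN]+$", x)

## A numeric that survives "." / "" / NULL as NA rather than an error.
num_or_na <- function(x) {
  if (length(x) == 0L || is.null(x)) return(NA_real_)
  suppressWarnings(out <- as.numeric(x))
  out
}

## Empty classified-call / canonical tables share one column layout.
param_cols <- c("vaf", "dp", "stb", "qual", "qd")

empty_canonical <- function() {
  data.frame(
    chrom = character(), start = integer(), end = integer(),
    ref = character(), alt = character(), vclass = character(),
    vaf = numeric(), dp = numeric(), stb = numeric(),
    qual = numeric(), qd = numeric(), key = character(),
    stringsAsFactors = FALSE
  )
}
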