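#' @keywords internal
#' @useDynLib esgamap, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## canonical unordered pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

## modal value of a continuous sample via kernel density; falls back to the
## median for very small samples where a density mode is unstable
modal_value <- function(x, min_n = 10L) {
  x <- x[is.finite(x)]
  if (length(x) < min_n) return(stats::median(x))
  d <- stats::density(x)
  m <- d$x[which.max(d$y)]
  if (!is.finite(m) || m <= 0) stats::median(x) else m
}

## column/row medians without matrixStats
col_medians <- function(m) apply(m, 2L, stats::median, na.rm = TRUE)
row_medians <- function(m) apply(m, 1L, stats::median, na.rm = TRUE)

## count of pooled null values >= x (exclusive-of-below semantics so that
## ties count as exceedances), given pre-sorted |null| values
count_geq <- function(x, sorted_abs) {
  length(sorted_abs) - findInterval(x, sorted_abs, left.open = TRUE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

## normalize an annotation input (two-column data.frame or named vector)
## to a named character vector gene -> bioprocess label
as_annotation <- function(annotations) {
  if (is.data.frame(annotations)) {
    cols <- intersect(c("gene", "bioprocess", "module"), names(annotations))
    if (length(cols) < 2L)
      stopf("annotation table needs columns 'gene' and 'bioprocess' (or 'module')")
    out <- as.character(annotations[[cols[2L]]])
    names(out) <- as.character(annotations[[cols[1L]]])
  } else {
    if (is.null(names(annotations))) stopf("annotations must be named by gene")
    out <- as.character(annotations)
    names(out) <- names(annotations)
  }
  if (anyDuplicated(names(out)))
    stopf("each gene must carry exactly one bioprocess label")
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
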