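# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonicalize chromosome names
#'
#' Reconciles the two common naming styles ("chr1" vs "1") to a single form so
#' that SNP catalogs and annotation tracks produced by different tools match.
#' The canonical form strips any leading "chr"/"Chr" prefix and upper-cases
#' the sex/mitochondrial labels, so "chr1" -> "1", "chrX" -> "X", "x" -> "X".
#'
#' @param x character vector of chromosome labels.
#' @return character vector of canonical labels.
#' @export
#' @examples
#' canonical_chrom(c("chr1", "1", "chrX", "x"))
canonical_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  sex <- x %in% c("x", "y", "m", "mt", "Mt")
  x[sex] <- toupper(x[sex])
  x
}

# Default ordered chromosome universe: autosomes 1..22 plus X.
default_chromosomes <- function() c(as.character(1:22), "X")

# Order chromosome labels: numeric first (by value), then lexicographic.
chrom_order <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  order(is.na(n), n, x)
}

stop_parse <- function(path, line, msg) {
  stop(sprintf("parse error in '%s' at line %d: %s", path, line, msg),
       call. = FALSE)
}

# Read a UTF-8 tab-delimited text file, skipping '#'-prefixed comment lines
# and UCSC "browser"/"track" header lines. Returns a list of character
# vectors (split fields) plus the original line numbers.
read_tab_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|browser\\b|track\\b)", lines) & nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

as_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("%s must be a single non-negative integer", what), call. = FALSE)
  as.integer(x)
}
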