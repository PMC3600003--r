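#' LD filter configuration
#'
#' Pairs enter the LD map only when their r-squared strictly exceeds
#' `r2_threshold` (matching the convention that partners at r2 > 0.9 are
#' effectively equivalent in association studies), they lie on the same
#' chromosome, and they are at most `max_pair_distance` base pairs apart on
#' either side (so two partners of one SNP can span up to twice that).
#'
#' @param r2_threshold r-squared threshold in (0, 1]; comparisons are strict
#'   (default 0.9; 0.7 is the common liberal alternative).
#' @param max_pair_distance maximum distance between partners in base pairs,
#'   per side (default 250000).
#' @return a list of class `ld_config`.
#' @export
ld_config <- function(r2_threshold = 0.9, max_pair_distance = 250000) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, max_pair_distance > 0)
  structure(list(r2_threshold = r2_threshold,
                 max_pair_distance = max_pair_distance),
            class = "ld_config")
}

#' Build an LD map from SNP pairs
#'
#' Filters pairs by the `ld_config` rules and stores the surviving partners as
#' a symmetric SNP -> partners mapping. Pairs referencing SNPs absent from the
#' catalog are dropped (with a warning reporting the count), as are
#' cross-chromosome pairs, which are invalid input for intra-chromosomal LD.
#'
#' @param pairs data frame with columns `snpA`, `snpB`, `r2`.
#' @param cfg an [ld_config()].
#' @param catalog a [snp_catalog()] supplying positions and chromosomes.
#' @return an object of class `ld_map`: a named list mapping each SNP id with
#'   at least one partner to the character vector of its partner ids.
#' @export
ld_map <- function(pairs, cfg = ld_config(), catalog) {
  stopifnot(is.data.frame(pairs), inherits(catalog, "snp_catalog"))
  need <- c("snpA", "snpB", "r2")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  r2 <- as.numeric(pairs$r2)
  if (any(is.na(r2) | r2 < 0 | r2 > 1))
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  ia <- match(pairs$snpA, catalog$snp_id)
  ib <- match(pairs$snpB, catalog$snp_id)
  unknown <- is.na(ia) | is.na(ib)
  if (any(unknown))
    warning(sprintf("dropped %d LD pair(s) referencing SNPs absent from the catalog",
                    sum(unknown)), call. = FALSE)
  cross <- !unknown & catalog$chrom[ia] != catalog$chrom[ib]
  if (any(cross))
    warning(sprintf("dropped %d cross-chromosome LD pair(s)", sum(cross)),
            call. = FALSE)
  keep <- !unknown & !cross &
    r2 > cfg$r2_threshold &
    abs(catalog$pos[ia] - catalog$pos[ib]) <= cfg$max_pair_distance &
    pairs$snpA != pairs$snpB
  a <- pairs$snpA[keep]; b <- pairs$snpB[keep]
  ids <- c(a, b); partners <- c(b, a)
  dup <- duplicated(paste(ids, partners))
  ids <- ids[!dup]; partners <- partners[!dup]
  m <- split(partners, factor(ids, levels = unique(ids)))
  structure(m, class = "ld_map", cfg = cfg)
}

#' Read LD pairs from a PLINK-.ld-like table
#'
#' Expects a tab-separated file with header columns `snpA`, `snpB`, `r2`
#' (extra columns ignored); `#`-prefixed comment lines are skipped.
#'
#' @param path file path.
#' @inheritParams ld_map
#' @return an [ld_map()].
#' @export
read_ld_pairs <- function(path, cfg = ld_config(), catalog) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ld_map(df, cfg, catalog)
}

#' LD partners of a SNP
#'
#' @param ld an [ld_map()].
#' @param snp_id a single SNP id.
#' @return character vector of partner ids (possibly empty).
#' @export
ld_partners <- function(ld, snp_id) {
  p <- ld[[snp_id]]
  if (is.null(p)) character(0) else p
}

#' LD-expanded SNP set
#'
#' The SNP together with all of its LD partners; SNPs without partners are
#' analyzed on their own, so the result is never empty.
#'
#' @param snp_id a single SNP id present in `catalog`.
#' @param ld an [ld_map()].
#' @param catalog a [snp_catalog()] (used to validate the id).
#' @return character vector: `snp_id` plus its partners.
#' @export
expand_with_ld <- function(snp_id, ld, catalog = NULL) {
  if (!is.null(catalog) && !(snp_id %in% catalog$snp_id))
    stop(sprintf("unknown SNP id '%s'", snp_id), call. = FALSE)
  unique(c(snp_id, ld_partners(ld, snp_id)))
}

#' @export
print.ld_map <- function(x, ...) {
  cat(sprintf("ld_map: %d SNP(s) with >=1 partner, %d directed links\n",
              length(x), sum(lengths(x))))
  invisible(x)
}
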