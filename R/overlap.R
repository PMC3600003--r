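#' Interval index for point membership queries
#'
#' Wraps a normalized [annotation_track()] in per-chromosome `IRanges` objects
#' so that "is this 1-based position inside the track?" is answered in
#' logarithmic time. Queries on chromosomes absent from the track are `FALSE`.
#'
#' @param track a normalized [annotation_track()].
#' @return an object of class `interval_index`.
#' @export
build_interval_index <- function(track) {
  stopifnot(inherits(track, "annotation_track"))
  parts <- split(seq_len(nrow(track)), track$chrom)
  # normalized tracks are sorted and disjoint per chromosome, so binary search
  # over the start vector (findInterval) answers point queries
  idx <- lapply(parts, function(i)
    list(start = track$start[i], end = track$end[i]))
  structure(list(chrom = idx, name = track_name(track)),
            class = "interval_index")
}

#' Query an interval index at 1-based positions
#'
#' A 1-based position p lies in the half-open interval [start, end) iff
#' start < p <= end.
#'
#' @param index an [build_interval_index()] result.
#' @param chrom chromosome labels (recycled against `pos`).
#' @param pos 1-based positions.
#' @return logical vector, one element per query.
#' @export
index_query <- function(index, chrom, pos) {
  stopifnot(inherits(index, "interval_index"))
  chrom <- canonical_chrom(chrom)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- logical(n)
  for (ch in unique(chrom)) {
    r <- index$chrom[[ch]]
    if (is.null(r)) next
    sel <- which(chrom == ch)
    p0 <- pos[sel] - 1  # 0-based coordinate of the 1-based position
    i <- findInterval(p0, r$start)
    out[sel] <- i >= 1 & p0 < r$end[pmax(i, 1L)]
  }
  out
}

#' LD-expanded SNP-by-annotation incidence matrix
#'
#' The unit every null model recounts: cell (s, t) is `TRUE` iff SNP s or any
#' of its LD partners lies inside track t. Incidence is binary - multiple
#' overlapping intervals or partners still count as one overlap. The matrix is
#' computed once and reused by all permutations and samples, so a permutation
#' is a relabelling, never a re-overlap.
#'
#' @param catalog a [snp_catalog()].
#' @param ld an [ld_map()]; partners absent from the catalog are ignored.
#' @param tracks list of [annotation_track()]s (or a single track).
#' @return logical matrix of class `overlap_matrix` with SNP ids as row names
#'   (catalog order), one column per track, and attributes `chrom` and `pos`
#'   mirroring the catalog.
#' @export
compute_overlap_matrix <- function(catalog, ld, tracks) {
  stopifnot(inherits(catalog, "snp_catalog"))
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)
  nms <- vapply(tracks, track_name, character(1), USE.NAMES = FALSE)
  n <- nrow(catalog)
  # Expanded query set: each SNP plus its partners, tagged by the owning row.
  pl <- vector("list", n)
  hit <- match(catalog$snp_id, names(ld))
  pl[!is.na(hit)] <- unclass(ld)[hit[!is.na(hit)]]
  owner <- c(seq_len(n), rep(seq_len(n), lengths(pl)))
  pidx <- match(unlist(pl), catalog$snp_id)
  known <- !is.na(pidx)
  owner <- c(owner[seq_len(n)], owner[-seq_len(n)][known])
  qpos <- c(catalog$pos, catalog$pos[pidx[known]])
  qchr <- c(catalog$chrom, catalog$chrom[pidx[known]])
  m <- matrix(FALSE, n, length(tracks), dimnames = list(catalog$snp_id, nms))
  # catalog chromosomes are already canonical; group queries by chromosome
  # once, then binary-search each track's sorted disjoint intervals
  sel_by_chr <- split(seq_along(qpos), qchr)
  for (j in seq_along(tracks)) {
    idx <- build_interval_index(tracks[[j]])
    inside <- logical(length(qpos))
    for (ch in names(sel_by_chr)) {
      r <- idx$chrom[[ch]]
      if (is.null(r)) next
      sel <- sel_by_chr[[ch]]
      p0 <- qpos[sel] - 1
      i <- findInterval(p0, r$start)
      inside[sel] <- i >= 1 & p0 < r$end[pmax(i, 1L)]
    }
    m[unique(owner[inside]), j] <- TRUE
  }
  structure(m, chrom = catalog$chrom, pos = catalog$pos,
            class = c("overlap_matrix", class(m)))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("overlap_matrix: %d SNPs x %d annotation(s)\n", nrow(x), ncol(x)))
  frac <- colMeans(x)
  for (j in seq_len(ncol(x)))
    cat(sprintf("  %-24s %5.1f%% of SNPs\n", colnames(x)[j], 100 * frac[j]))
  invisible(x)
}

#' Write / read an overlap matrix as dense 0/1 TSV
#'
#' @param matrix an [compute_overlap_matrix()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_overlap_matrix <- function(matrix, path) {
  df <- data.frame(snp_id = rownames(matrix),
                   chrom = attr(matrix, "chrom"),
                   pos = attr(matrix, "pos"),
                   `+`(matrix * 1L, 0L), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_overlap_matrix
#' @export
read_overlap_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("snp_id", "chrom", "pos")
  stopifnot(all(meta %in% names(df)))
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE]) > 0
  rownames(m) <- df$snp_id
  structure(m, chrom = canonical_chrom(df$chrom), pos = as.numeric(df$pos),
            class = c("overlap_matrix", class(m)))
}
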