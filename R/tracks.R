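#' Annotation track
#'
#' A named set of genomic intervals in 0-based half-open coordinates
#' ([start, end)), normalized on construction: within each chromosome the
#' intervals are sorted and overlapping or touching intervals are merged.
#'
#' @param name track name.
#' @param chrom chromosome labels.
#' @param start 0-based interval starts.
#' @param end interval ends (exclusive); must satisfy `start < end`.
#' @param strand optional strand (`"+"`/`"-"`), kept only for TSS tracks;
#'   normalization is skipped when strand is present since direction matters
#'   per site.
#' @return data frame of class `annotation_track` with attribute `name`.
#' @export
annotation_track <- function(name, chrom = character(), start = numeric(),
                             end = numeric(), strand = NULL) {
  if (length(chrom) == 1L && length(start) > 1L)
    chrom <- rep_len(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  chrom <- canonical_chrom(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start) | is.na(end) | start < 0 | start >= end))
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  if (is.null(strand)) {
    df <- normalize_intervals(data.frame(chrom = chrom, start = start, end = end,
                                         stringsAsFactors = FALSE))
  } else {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-")))
      stop("strand must be '+' or '-'", call. = FALSE)
    df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                     stringsAsFactors = FALSE)
    df <- df[order(match(df$chrom, unique(df$chrom)[chrom_order(unique(df$chrom))]),
                   df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, name = as.character(name),
            class = c("annotation_track", "data.frame"))
}

# Sort and merge (touching intervals merged) via IRanges::reduce per chromosome.
normalize_intervals <- function(df) {
  if (!nrow(df)) {
    rownames(df) <- NULL
    return(df)
  }
  parts <- split(seq_len(nrow(df)), df$chrom)
  out <- lapply(names(parts), function(ch) {
    i <- parts[[ch]]
    # IRanges is 1-based closed; [start, end) maps to IRanges(start + 1, end)
    r <- IRanges::reduce(IRanges::IRanges(df$start[i] + 1, df$end[i]))
    data.frame(chrom = ch, start = BiocGenerics::start(r) - 1,
               end = BiocGenerics::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$chrom, unique(out$chrom)[chrom_order(unique(out$chrom))]),
                   out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("annotation_track '%s': %d interval(s), %s bp covered\n",
              attr(x, "name"), nrow(x),
              format(sum(x$end - x$start), big.mark = ",")))
  invisible(x)
}

#' Track name
#' @param track an [annotation_track()].
#' @return the track's name.
#' @export
track_name <- function(track) attr(track, "name")

#' Read an annotation track from a BED file
#'
#' Accepts BED3+ (extra columns ignored). Header lines starting with `#`,
#' `browser` or `track` are skipped. Coordinates are validated per line:
#' non-integer values or `start >= end` raise a parse error naming the line.
#'
#' @param path file path.
#' @param name track name (defaults to the file stem).
#' @return a normalized [annotation_track()].
#' @export
read_annotation_bed <- function(path, name = sub("\\.bed$", "", basename(path))) {
  parsed <- read_tab_lines(path)
  n <- length(parsed$fields)
  if (!n) return(annotation_track(name))
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  for (k in seq_len(n)) {
    f <- parsed$fields[[k]]
    if (length(f) < 3)
      stop_parse(path, parsed$lineno[k], "expected >= 3 tab-separated fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e))
      stop_parse(path, parsed$lineno[k],
                 sprintf("non-integer coordinates '%s', '%s'", f[2], f[3]))
    if (s >= e)
      stop_parse(path, parsed$lineno[k],
                 sprintf("inverted or empty interval [%s, %s)", f[2], f[3]))
    if (s < 0) stop_parse(path, parsed$lineno[k], "negative start coordinate")
    chrom[k] <- f[1]; start[k] <- s; end[k] <- e
  }
  annotation_track(name, chrom, start, end)
}

#' Read a TSS track from a BED6 file
#'
#' Like [read_annotation_bed()] but requires a strand column (field 6) and
#' keeps one record per site without merging, since the transcription start
#' site and its direction are what matter.
#'
#' @param path file path.
#' @param name track name.
#' @return an [annotation_track()] with a `strand` column.
#' @export
read_tss_bed <- function(path, name = sub("\\.bed$", "", basename(path))) {
  parsed <- read_tab_lines(path)
  n <- length(parsed$fields)
  if (!n) stop("TSS track is empty", call. = FALSE)
  chrom <- character(n); start <- numeric(n); end <- numeric(n); strand <- character(n)
  for (k in seq_len(n)) {
    f <- parsed$fields[[k]]
    if (length(f) < 6)
      stop_parse(path, parsed$lineno[k], "TSS BED needs >= 6 fields (strand in field 6)")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s >= e)
      stop_parse(path, parsed$lineno[k], "malformed coordinates")
    chrom[k] <- f[1]; start[k] <- s; end[k] <- e; strand[k] <- f[6]
  }
  annotation_track(name, chrom, start, end, strand = strand)
}

#' Write an annotation track as BED3
#'
#' @param track an [annotation_track()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_annotation_bed <- function(track, path) {
  df <- as.data.frame(track)[, c("chrom", "start", "end")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Subtract tracks
#'
#' Removes from `base` every base pair covered by any of the `exclusions`.
#' This is how the negative-control annotation is built: intergenic sequence
#' minus all genic, regulatory and evolutionary annotation.
#'
#' @param base an [annotation_track()].
#' @param exclusions list of [annotation_track()]s to subtract.
#' @param name name for the derived track.
#' @return a normalized [annotation_track()] covering `base` minus the union
#'   of the exclusions.
#' @export
subtract_tracks <- function(base, exclusions,
                            name = paste0(track_name(base), "_negative")) {
  stopifnot(inherits(base, "annotation_track"))
  if (inherits(exclusions, "annotation_track")) exclusions <- list(exclusions)
  excl <- do.call(rbind, lapply(exclusions, function(t)
    as.data.frame(t)[, c("chrom", "start", "end")]))
  if (is.null(excl) || !nrow(excl)) {
    return(annotation_track(name, base$chrom, base$start, base$end))
  }
  chroms <- unique(base$chrom)
  out <- lapply(chroms, function(ch) {
    b <- base[base$chrom == ch, , drop = FALSE]
    e <- excl[excl$chrom == ch, , drop = FALSE]
    br <- IRanges::IRanges(b$start + 1, b$end)
    if (!nrow(e)) {
      r <- IRanges::reduce(br)
    } else {
      er <- IRanges::reduce(IRanges::IRanges(e$start + 1, e$end))
      r <- BiocGenerics::setdiff(br, er)
    }
    if (!length(r)) return(NULL)
    data.frame(chrom = ch, start = BiocGenerics::start(r) - 1,
               end = BiocGenerics::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    annotation_track(name)
  else
    annotation_track(name, out$chrom, out$start, out$end)
}

#' Total base pairs covered by a track
#' @param track an [annotation_track()].
#' @return total covered length in base pairs.
#' @export
track_coverage_bp <- function(track) sum(track$end - track$start)
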