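# Independent brute-force oracles and tiny fixture builders. These never call
# the fast paths they are used to check.

# Per-base membership oracle: is 1-based position p inside any [start, end)
# interval of the track, by linear scan?
brute_point_in_track <- function(track, chrom, pos) {
  any(track$chrom == chrom & track$start < pos & pos <= track$end)
}

# Brute-force LD-expanded overlap of one SNP against one track.
brute_snp_overlap <- function(catalog, ld, track, snp_id) {
  ids <- unique(c(snp_id, if (!is.null(ld[[snp_id]])) ld[[snp_id]]))
  rows <- match(ids, catalog$snp_id)
  rows <- rows[!is.na(rows)]
  any(vapply(rows, function(r)
    brute_point_in_track(track, catalog$chrom[r], catalog$pos[r]), logical(1)))
}

# Brute-force overlap matrix by nested loops over (SNP, partner, interval).
brute_overlap_matrix <- function(catalog, ld, tracks) {
  m <- matrix(FALSE, nrow(catalog), length(tracks),
              dimnames = list(catalog$snp_id,
                              vapply(tracks, track_name, character(1),
                                     USE.NAMES = FALSE)))
  for (i in seq_len(nrow(catalog)))
    for (j in seq_along(tracks))
      m[i, j] <- brute_snp_overlap(catalog, ld, tracks[[j]], catalog$snp_id[i])
  m
}

# Per-base subtraction oracle on a small chromosome: enumerate covered bases.
brute_subtract_bases <- function(base, exclusions, chrom, max_bp) {
  covered <- rep(FALSE, max_bp)
  for (i in which(base$chrom == chrom))
    covered[(base$start[i] + 1):base$end[i]] <- TRUE
  for (ex in exclusions)
    for (i in which(ex$chrom == chrom))
      covered[(ex$start[i] + 1):min(ex$end[i], max_bp)] <- FALSE
  which(covered)  # 1-based positions of covered bases
}

# Bases covered by a track on one chromosome (1-based positions).
track_bases <- function(track, chrom, max_bp) {
  covered <- rep(FALSE, max_bp)
  for (i in which(track$chrom == chrom))
    covered[(track$start[i] + 1):min(track$end[i], max_bp)] <- TRUE
  which(covered)
}

# Brute-force permutation recount: rotate the labels with
# circular_shift_labels, then re-derive the LD-expanded overlap for every
# relabelled SNP from the raw intervals (no reuse of the overlap matrix).
brute_permutation_counts <- function(catalog, ld, tracks, status, offsets) {
  chroms <- colnames(offsets)
  n_perm <- nrow(offsets)
  counts <- matrix(0, n_perm, length(tracks),
                   dimnames = list(NULL, vapply(tracks, track_name, character(1),
                                                USE.NAMES = FALSE)))
  # cache each SNP's brute overlap row: recomputed from intervals, not taken
  # from the package's matrix
  snp_overlap <- brute_overlap_matrix(catalog, ld, tracks)
  for (p in seq_len(n_perm)) {
    lab <- logical(nrow(catalog))
    for (ch in chroms) {
      rows <- which(catalog$chrom == ch)
      nk <- length(rows)
      # index-arithmetic rotation: element i moves to (i + offset - 1) mod n + 1
      dest <- (seq_len(nk) + offsets[p, ch] - 1) %% nk + 1
      lab[rows[dest]] <- status[rows]
    }
    counts[p, ] <- colSums(snp_overlap[lab, , drop = FALSE])
  }
  counts
}

# Small deterministic catalog on two chromosomes.
tiny_catalog <- function() {
  snp_catalog(snp_id = paste0("s", 1:8),
              chrom = c("1", "1", "1", "1", "2", "2", "2", "2"),
              pos = c(100, 150, 300, 900, 50, 120, 400, 800),
              platforms = rep(c("affy", "illu,affy"), 4))
}

tiny_track <- function(name = "t1",
                       chrom = c("1", "2"),
                       start = c(90, 100),
                       end = c(160, 150)) {
  annotation_track(name, chrom, start, end)
}

# Write lines to a temp file and return its path.
tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
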