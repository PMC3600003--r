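#' Synthetic study configuration
#'
#' Defines a toy genome with the statistical structure the enrichment methods
#' face on real data: clustered SNP positions, block-structured LD with a hard
#' distance cap, clustered annotation tracks of configurable coverage,
#' platform-group labels, and association labels planted at a target odds
#' ratio relative to chosen tracks.
#'
#' All generators consume a single seeded stream, in this order: SNP positions
#' (chromosome by chromosome), platform flags, LD block boundaries and pair
#' r-squared values (chromosome by chromosome), annotation intervals (track by
#' track), association labels.
#'
#' @param n_chromosomes number of chromosomes (default 3).
#' @param snps_per_chromosome SNPs per chromosome (default 20000).
#' @param chromosome_length chromosome length in base pairs (default 2e7,
#'   matching the real ~1 SNP/kb marker density).
#' @param cluster_size_mean mean number of SNPs per position cluster
#'   (default 20).
#' @param cluster_gap_mean mean within-cluster gap in base pairs (default 300;
#'   gaps are geometric, cluster centers uniform - a Poisson cluster process).
#' @param ld_block_length mean LD block length in base pairs (default 20000;
#'   block lengths are exponential).
#' @param within_block_r2 function(n) drawing n r-squared values for
#'   within-block SNP pairs (default uniform on \[0.5, 1\], so roughly a fifth
#'   of intra-block pairs pass the default 0.9 threshold).
#' @param ld_cfg an [ld_config()] applied when building the LD map.
#' @param tracks data frame with columns `name`, `coverage` (target fraction
#'   of the genome), `len_mean` (mean interval length, bp) and `cluster`
#'   (intervals per cluster center); default 10 tracks spanning coverages
#'   0.02-0.20.
#' @param n_assoc number of trait-associated SNPs to plant (default 500).
#' @param planted_or named numeric vector mapping track names to target odds
#'   ratios (default `c(feat03 = 2)`); use 1 everywhere for a null genome.
#' @param platform_groups named numeric vector of per-group inclusion
#'   probabilities (default affymetrix 0.4, illumina 0.4, hapmap 0.6); SNPs
#'   drawn into no group are assigned to `"hapmap"`, mirroring the role of the
#'   imputation panel as the catch-all platform.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 3,
                       snps_per_chromosome = 20000,
                       chromosome_length = 2e7,
                       cluster_size_mean = 20,
                       cluster_gap_mean = 300,
                       ld_block_length = 20000,
                       within_block_r2 = function(n) stats::runif(n, 0.5, 1),
                       ld_cfg = ld_config(),
                       tracks = default_sim_tracks(),
                       n_assoc = 500,
                       planted_or = c(feat03 = 2),
                       platform_groups = c(affymetrix = 0.4, illumina = 0.4,
                                           hapmap = 0.6),
                       seed = 1L) {
  stopifnot(n_chromosomes >= 1, snps_per_chromosome >= 0,
            chromosome_length > 0, is.function(within_block_r2),
            is.data.frame(tracks),
            all(c("name", "coverage", "len_mean", "cluster") %in% names(tracks)))
  if (any(tracks$coverage <= 0 | tracks$coverage >= 1))
    stop("track coverage fractions must lie in (0, 1)", call. = FALSE)
  if (any(planted_or <= 0)) stop("planted_or values must be > 0", call. = FALSE)
  if (n_assoc >= n_chromosomes * snps_per_chromosome && snps_per_chromosome > 0)
    stop("n_assoc must be below the total SNP count", call. = FALSE)
  structure(list(n_chromosomes = n_chromosomes,
                 snps_per_chromosome = snps_per_chromosome,
                 chromosome_length = chromosome_length,
                 cluster_size_mean = cluster_size_mean,
                 cluster_gap_mean = cluster_gap_mean,
                 ld_block_length = ld_block_length,
                 within_block_r2 = within_block_r2,
                 ld_cfg = ld_cfg, tracks = tracks, n_assoc = n_assoc,
                 planted_or = planted_or, platform_groups = platform_groups,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default synthetic annotation-track layout
#' @return data frame describing 10 clustered tracks with coverages 0.02-0.20.
#' @export
default_sim_tracks <- function() {
  data.frame(name = sprintf("feat%02d", 1:10),
             coverage = seq(0.02, 0.20, length.out = 10),
             len_mean = 5000, cluster = 5, stringsAsFactors = FALSE)
}

#' Simulate a clustered SNP catalog
#'
#' SNP positions come from a Poisson cluster process: cluster centers uniform
#' on the chromosome, cluster sizes Poisson around the configured mean, and
#' within-cluster gaps geometric - over-dispersed relative to a uniform
#' (Poisson) placement, as real marker maps are. Positions are deduplicated
#' and sorted; platform flags are independent Bernoulli draws per group with a
#' "hapmap" fallback so every SNP belongs to at least one group.
#'
#' @param cfg a [sim_config()]. The random stream must already be seeded when
#'   called directly from [simulate_study()]; calling this function alone
#'   seeds from `cfg$seed`.
#' @param .seeded internal: skip re-seeding when part of a pipeline.
#' @return a [snp_catalog()].
#' @export
simulate_genome <- function(cfg = sim_config(), .seeded = FALSE) {
  if (!.seeded) set.seed(cfg$seed)
  if (cfg$snps_per_chromosome > cfg$chromosome_length)
    stop("requested SNPs exceed chromosome capacity", call. = FALSE)
  if (cfg$snps_per_chromosome == 0) {
    return(snp_catalog(character(0), character(0), numeric(0), character(0)))
  }
  chroms <- as.character(seq_len(cfg$n_chromosomes))
  per <- lapply(chroms, function(ch) {
    pos <- numeric(0)
    gap_p <- 1 / max(cfg$cluster_gap_mean, 1)
    while (length(pos) < cfg$snps_per_chromosome) {
      need <- cfg$snps_per_chromosome - length(pos)
      n_clust <- max(1L, ceiling(need / cfg$cluster_size_mean))
      centers <- ceiling(stats::runif(n_clust) * cfg$chromosome_length)
      sizes <- 1L + stats::rpois(n_clust, cfg$cluster_size_mean - 1)
      new <- unlist(lapply(seq_len(n_clust), function(i) {
        centers[i] + cumsum(1 + stats::rgeom(sizes[i], gap_p))
      }))
      pos <- unique(c(pos, new[new >= 1 & new <= cfg$chromosome_length]))
    }
    # subsample (not truncate) any surplus so no region is favored
    if (length(pos) > cfg$snps_per_chromosome)
      pos <- pos[sort(sample.int(length(pos), cfg$snps_per_chromosome))]
    sort(pos)
  })
  n <- cfg$n_chromosomes * cfg$snps_per_chromosome
  groups <- names(cfg$platform_groups)
  member <- vapply(cfg$platform_groups, function(p) stats::runif(n) < p,
                   logical(n))
  if (is.null(dim(member))) member <- base::matrix(member, nrow = n)
  none <- rowSums(member) == 0
  fallback <- if ("hapmap" %in% groups) "hapmap" else groups[1]
  member[none, match(fallback, groups)] <- TRUE
  platforms <- apply(member, 1, function(r) paste(groups[r], collapse = ","))
  snp_catalog(sprintf("rs%06d", seq_len(n)),
              rep(chroms, each = cfg$snps_per_chromosome),
              unlist(per), platforms)
}

#' Simulate block-structured LD
#'
#' Each chromosome is tiled into blocks of exponential length (mean
#' `ld_block_length`); every SNP pair within a block receives an r-squared
#' from `within_block_r2`; no cross-block partners exist. Only pairs passing
#' the `ld_cfg` filters (r2 strictly above threshold, within the distance cap)
#' enter the map.
#'
#' @param catalog a [snp_catalog()].
#' @param cfg a [sim_config()].
#' @param .seeded internal: skip re-seeding when part of a pipeline.
#' @return an [ld_map()].
#' @export
simulate_ld_blocks <- function(catalog, cfg = sim_config(), .seeded = FALSE) {
  if (!.seeded) set.seed(cfg$seed)
  stopifnot(inherits(catalog, "snp_catalog"))
  ia <- integer(0); ib <- integer(0)
  for (ch in unique(catalog$chrom)) {
    rows <- which(catalog$chrom == ch)
    pos <- catalog$pos[rows]
    # tile the chromosome into exponential-length blocks
    n_b <- ceiling(2 * cfg$chromosome_length / cfg$ld_block_length) + 10L
    bounds <- cumsum(stats::rexp(n_b, 1 / cfg$ld_block_length))
    while (utils::tail(bounds, 1) < cfg$chromosome_length)
      bounds <- c(bounds, utils::tail(bounds, 1) +
                    cumsum(stats::rexp(n_b, 1 / cfg$ld_block_length)))
    block <- findInterval(pos, c(0, bounds))
    # all intra-block index pairs, vectorized over runs of equal block id
    r <- rle(block)
    m <- r$lengths
    first <- cumsum(c(0L, m[-length(m)]))  # 0-based offset of each run
    mm <- m[m >= 2]; ff <- first[m >= 2]
    if (!length(mm)) next
    a <- unlist(lapply(seq_along(mm), function(k) {
      mk <- mm[k]
      ff[k] + rep.int(seq_len(mk - 1L), (mk - 1L):1L)
    }))
    b <- unlist(lapply(seq_along(mm), function(k) {
      mk <- mm[k]
      ff[k] + sequence((mk - 1L):1L) + rep.int(seq_len(mk - 1L), (mk - 1L):1L)
    }))
    ia <- c(ia, rows[a]); ib <- c(ib, rows[b])
  }
  pairs <- data.frame(snpA = catalog$snp_id[ia], snpB = catalog$snp_id[ib],
                      r2 = if (length(ia)) cfg$within_block_r2(length(ia))
                           else numeric(0),
                      stringsAsFactors = FALSE)
  ld_map(pairs, cfg$ld_cfg, catalog)
}

#' Simulate clustered annotation tracks
#'
#' Intervals are placed around uniform cluster centers (`cluster` intervals
#' per center, exponential lengths with mean `len_mean`, geometric spacing)
#' and added until the realized merged coverage is within +/-10% relative of
#' the target; overshoot is trimmed by dropping the last batch and adding
#' single intervals. Unreachable targets (no progress over many rounds) raise
#' an error.
#'
#' @param cfg a [sim_config()].
#' @param .seeded internal: skip re-seeding when part of a pipeline.
#' @return named list of [annotation_track()]s.
#' @export
simulate_annotations <- function(cfg = sim_config(), .seeded = FALSE) {
  if (!.seeded) set.seed(cfg$seed)
  L <- cfg$chromosome_length
  genome_bp <- cfg$n_chromosomes * L
  chroms <- as.character(seq_len(cfg$n_chromosomes))
  out <- list()
  for (t in seq_len(nrow(cfg$tracks))) {
    spec <- cfg$tracks[t, ]
    target <- spec$coverage * genome_bp
    df <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    covered <- 0
    rounds <- 0L
    repeat {
      rounds <- rounds + 1L
      if (rounds > 200L)
        stop(sprintf("track '%s': coverage target %.3f unreachable",
                     spec$name, spec$coverage), call. = FALSE)
      gap <- target - covered
      if (abs(gap) <= 0.1 * target && covered > 0) break
      # batch size shrinks as we approach the target
      n_new <- max(1L, floor(0.7 * gap / (spec$len_mean * spec$cluster)))
      centers_ch <- sample(chroms, n_new, replace = TRUE)
      starts <- ceiling(stats::runif(n_new) * L)
      k <- spec$cluster
      # within-cluster interval starts: cumulative (gap + length) offsets
      off <- if (k > 1) {
        g <- base::matrix(stats::rgeom((k - 1) * n_new, 1 / (2 * spec$len_mean)) +
                            stats::rexp((k - 1) * n_new, 1 / spec$len_mean),
                          k - 1, n_new)
        rbind(0, apply(g, 2, cumsum))
      } else base::matrix(0, 1, n_new)
      s <- rep(starts, each = k) + as.numeric(off)
      len <- pmax(1, stats::rexp(k * n_new, 1 / spec$len_mean))
      e <- pmin(s + len, L)
      ok <- s >= 0 & s < e
      df <- rbind(df, data.frame(chrom = rep(centers_ch, each = k)[ok],
                                 start = floor(s[ok]), end = ceiling(e[ok]),
                                 stringsAsFactors = FALSE))
      df <- normalize_intervals(df)
      covered <- sum(df$end - df$start)
      if (covered > target * 1.1) {
        # overshoot: drop intervals from the end until inside the band
        while (covered > target * 1.1 && nrow(df) > 1) {
          covered <- covered - (df$end[nrow(df)] - df$start[nrow(df)])
          df <- df[-nrow(df), , drop = FALSE]
        }
        break
      }
    }
    out[[spec$name]] <- annotation_track(spec$name, df$chrom, df$start, df$end)
  }
  out
}

#' Plant association labels at a target odds ratio
#'
#' Association labels are drawn without replacement with per-SNP weights
#' `prod(planted_or ^ incidence)` over the designated tracks (exponential
#' tilting by incidence). As the genome grows and association stays rare, the
#' realized conditional odds ratio for each designated track approaches its
#' target. The realized 2x2 table per track is returned as ground truth so
#' downstream checks compare against the realized, not nominal, odds ratio.
#'
#' @param matrix an [compute_overlap_matrix()] result containing the target
#'   track columns.
#' @param cfg a [sim_config()] (uses `n_assoc` and `planted_or`).
#' @param .seeded internal: skip re-seeding when part of a pipeline.
#' @return list with `status` (logical per SNP), `tables` (named list of
#'   realized contingency tables: assoc/non-assoc x in/out of track) and
#'   `realized_or` (named numeric).
#' @export
plant_associations <- function(matrix, cfg = sim_config(), .seeded = FALSE) {
  if (!.seeded) set.seed(cfg$seed)
  n <- nrow(matrix)
  if (cfg$n_assoc > n) stop("n_assoc exceeds the number of SNPs", call. = FALSE)
  w <- rep(1, n)
  for (tr in names(cfg$planted_or)) {
    if (!(tr %in% colnames(matrix)))
      stop(sprintf("planted track '%s' absent from matrix", tr), call. = FALSE)
    w <- w * cfg$planted_or[[tr]] ^ (matrix[, tr])
  }
  status <- logical(n)
  # Efraimidis-Spirakis keys: taking the n_assoc largest u^(1/w) is
  # distributionally identical to sequential weighted sampling without
  # replacement, at O(n log n) instead of O(n * n_assoc)
  keys <- stats::runif(n) ^ (1 / w)
  status[order(keys, decreasing = TRUE)[seq_len(cfg$n_assoc)]] <- TRUE
  tables <- lapply(stats::setNames(nm = names(cfg$planted_or)), function(tr) {
    x <- matrix[, tr]
    contingency_table(sum(status & x), sum(status & !x),
                      sum(!status & x), sum(!status & !x))
  })
  realized <- vapply(tables, function(tb)
    tryCatch(odds_ratio(tb), error = function(e) NaN), numeric(1))
  list(status = status, tables = tables, realized_or = realized)
}

#' Simulate a complete study
#'
#' Runs the full generator stack under one seed: genome, LD blocks,
#' annotation tracks, overlap matrix, planted association labels.
#'
#' @param cfg a [sim_config()].
#' @return list with `catalog`, `ld`, `tracks`, `matrix`, `status`, `truth`
#'   (the [plant_associations()] ground-truth object) and `cfg`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  catalog <- simulate_genome(cfg, .seeded = TRUE)
  ld <- suppressWarnings(simulate_ld_blocks(catalog, cfg, .seeded = TRUE))
  tracks <- simulate_annotations(cfg, .seeded = TRUE)
  mat <- compute_overlap_matrix(catalog, ld, tracks)
  truth <- plant_associations(mat, cfg, .seeded = TRUE)
  list(catalog = catalog, ld = ld, tracks = tracks, matrix = mat,
       status = truth$status, truth = truth, cfg = cfg)
}
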