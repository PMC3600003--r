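#' SNP catalog
#'
#' A `snp_catalog` is the substrate every null model permutes or samples: an
#' ordered per-chromosome list of SNPs with 1-based positions, platform-group
#' membership, optional association P-values and an association status. SNP
#' positions follow the dbSNP/VCF convention (1-based); annotation intervals
#' are 0-based half-open, so a position p lies in interval [start, end) iff
#' start < p <= end.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome labels (canonicalized with [canonical_chrom()]).
#' @param pos 1-based positions in base pairs.
#' @param platforms character vector of comma-joined platform-group labels,
#'   one element per SNP; every SNP must belong to at least one group. The
#'   special group `"hapmap"` marks SNPs present only through imputation
#'   panels.
#' @param pvalue optional association P-values in (0, 1]; `NA` for SNPs with
#'   no reported association.
#' @param status optional association status, one of `"background"`,
#'   `"suggestive"`, `"significant"`; defaults to `"background"`.
#' @return a data frame of class `snp_catalog`, sorted by (chromosome,
#'   position), with columns `snp_id`, `chrom`, `pos`, `platforms`, `pvalue`,
#'   `status`, `demoted`.
#' @seealso [read_snp_table()], [assign_association_status()]
#' @export
snp_catalog <- function(snp_id, chrom, pos, platforms,
                        pvalue = NA_real_, status = "background") {
  n <- length(snp_id)
  stopifnot(length(chrom) == n, length(pos) == n, length(platforms) == n)
  chrom <- canonical_chrom(chrom)
  pos <- as.numeric(pos)
  if (anyNA(pos) || any(pos <= 0) || any(pos != floor(pos)))
    stop("positions must be positive integers (1-based)", call. = FALSE)
  if (anyDuplicated(snp_id))
    stop("duplicate snp_id values: ",
         paste(unique(snp_id[duplicated(snp_id)])[1:min(3, n)], collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(trimws(platforms))))
    stop("every SNP must belong to at least one platform group", call. = FALSE)
  if (anyDuplicated(paste(chrom, pos, snp_id)))
    stop("duplicate (chromosome, position, snp_id) triples", call. = FALSE)
  pvalue <- rep_len(as.numeric(pvalue), n)
  if (any(!is.na(pvalue) & (pvalue <= 0 | pvalue > 1)))
    stop("assoc_pvalue must lie in (0, 1]", call. = FALSE)
  status <- rep_len(as.character(status), n)
  bad <- setdiff(unique(status), c("background", "suggestive", "significant"))
  if (length(bad)) stop("unknown status: ", bad[1], call. = FALSE)
  cat <- data.frame(snp_id = as.character(snp_id), chrom = chrom, pos = pos,
                    platforms = as.character(platforms), pvalue = pvalue,
                    status = status, demoted = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  o <- order(match(cat$chrom, unique(cat$chrom)[chrom_order(unique(cat$chrom))]),
             cat$pos)
  cat <- cat[o, , drop = FALSE]
  rownames(cat) <- NULL
  class(cat) <- c("snp_catalog", "data.frame")
  cat
}

#' @export
print.snp_catalog <- function(x, ...) {
  cat(sprintf("snp_catalog: %d SNPs on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  tab <- table(x$status)
  cat("  status:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read a SNP catalog from a tab-separated table
#'
#' Expects a header with columns `snp_id`, `chrom`, `pos`, `platform_groups`
#' (comma-joined labels) and optionally `pvalue`. Rows are re-sorted into
#' (chromosome, position) order. Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return a [snp_catalog()].
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("snp_id", "chrom", "pos", "platform_groups")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  pos <- suppressWarnings(as.numeric(df$pos))
  if (anyNA(pos)) stop_parse(path, which(is.na(pos))[1] + 1L,
                             sprintf("non-numeric position '%s'", df$pos[which(is.na(pos))[1]]))
  pv <- if ("pvalue" %in% names(df)) suppressWarnings(as.numeric(df$pvalue)) else NA_real_
  snp_catalog(df$snp_id, df$chrom, pos, df$platform_groups, pvalue = pv)
}

#' Write a SNP catalog as a tab-separated table
#'
#' @param catalog a [snp_catalog()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_snp_table <- function(catalog, path) {
  df <- data.frame(snp_id = catalog$snp_id, chrom = catalog$chrom,
                   pos = format(catalog$pos, scientific = FALSE, trim = TRUE),
                   platform_groups = catalog$platforms,
                   pvalue = catalog$pvalue)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Association status thresholds
#'
#' Configuration for mapping association P-values onto the three-way status
#' used throughout: genome-wide significant (p < `genomewide_threshold`),
#' suggestive (`genomewide_threshold` <= p < `suggestive_upper`), background
#' otherwise. SNPs on `excluded_chromosomes` are removed before assignment,
#' and suggestive SNPs in LD (r-squared above `prune_suggestive_r2`) with any
#' significant SNP are demoted to background.
#'
#' @param genomewide_threshold genome-wide significance threshold
#'   (default 5e-8).
#' @param suggestive_upper upper bound of the suggestive window (default 5e-5).
#' @param excluded_chromosomes chromosome labels removed from all analyses
#'   (default Y and unassigned/"Un").
#' @param prune_suggestive_r2 r-squared threshold used when demoting
#'   suggestive SNPs in LD with significant ones (default 0.9).
#' @return a list of class `status_config`.
#' @export
status_config <- function(genomewide_threshold = 5e-8,
                          suggestive_upper = 5e-5,
                          excluded_chromosomes = c("Y", "Un", "unassigned"),
                          prune_suggestive_r2 = 0.9) {
  stopifnot(genomewide_threshold > 0, suggestive_upper <= 1)
  if (!(genomewide_threshold < suggestive_upper))
    stop("genomewide_threshold must be below suggestive_upper", call. = FALSE)
  structure(list(genomewide_threshold = genomewide_threshold,
                 suggestive_upper = suggestive_upper,
                 excluded_chromosomes = canonical_chrom(excluded_chromosomes),
                 prune_suggestive_r2 = prune_suggestive_r2),
            class = "status_config")
}

#' Assign association status from P-values
#'
#' Removes SNPs on excluded chromosomes, classifies the rest by P-value, and
#' demotes suggestive SNPs that are in LD with any significant SNP (direct LD
#' partnership only, no transitive closure) to background, flagging them in
#' the `demoted` column. The operation is idempotent.
#'
#' @param catalog a [snp_catalog()] with `pvalue` populated for candidate
#'   trait SNPs (`NA` means no reported association).
#' @param cfg a [status_config()].
#' @param ld an [ld_map()] used for the suggestive-set pruning; may be `NULL`
#'   to skip pruning.
#' @return the catalog with `status` (and `demoted`) updated and excluded
#'   chromosomes removed.
#' @export
assign_association_status <- function(catalog, cfg = status_config(), ld = NULL) {
  stopifnot(inherits(catalog, "snp_catalog"))
  keep <- !(catalog$chrom %in% cfg$excluded_chromosomes)
  catalog <- catalog[keep, , drop = FALSE]
  p <- catalog$pvalue
  status <- rep("background", nrow(catalog))
  status[!is.na(p) & p < cfg$genomewide_threshold] <- "significant"
  status[!is.na(p) & p >= cfg$genomewide_threshold &
           p < cfg$suggestive_upper] <- "suggestive"
  demoted <- rep(FALSE, nrow(catalog))
  if (!is.null(ld)) {
    sig_ids <- catalog$snp_id[status == "significant"]
    sug <- which(status == "suggestive")
    if (length(sig_ids) && length(sug)) {
      hit <- vapply(catalog$snp_id[sug], function(id) {
        any(ld_partners(ld, id) %in% sig_ids)
      }, logical(1))
      demoted[sug[hit]] <- TRUE
      status[sug[hit]] <- "background"
    }
  }
  catalog$status <- status
  catalog$demoted <- demoted
  rownames(catalog) <- NULL
  class(catalog) <- c("snp_catalog", "data.frame")
  catalog
}

# Logical matrix SNP x platform-group, from the comma-joined platforms column.
#' Platform membership matrix
#'
#' @param catalog a [snp_catalog()].
#' @return logical matrix with one row per SNP (catalog order) and one column
#'   per platform group, `TRUE` where the SNP belongs to the group.
#' @export
platform_matrix <- function(catalog) {
  lst <- strsplit(catalog$platforms, ",", fixed = TRUE)
  lst <- lapply(lst, trimws)
  groups <- sort(unique(unlist(lst)))
  m <- matrix(FALSE, nrow(catalog), length(groups),
              dimnames = list(catalog$snp_id, groups))
  m[cbind(rep(seq_along(lst), lengths(lst)), match(unlist(lst), groups))] <- TRUE
  m
}
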