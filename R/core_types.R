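#' Construct a haplotype panel
#'
#' The central container: a phased allele matrix (haplotypes x biallelic
#' sites) with per-site metadata and per-haplotype group labels.  Modern
#' samples contribute two phased haplotype rows each; archaic genomes are
#' unphased and contribute two genotype rows that collapse to one
#' pseudo-haplotype once archaic-heterozygous sites are removed (see
#' [collapse_archaics()]).
#'
#' @param alleles integer matrix, rows = haplotypes, cols = sites; entries
#'   0 (ref), 1 (alt) or `NA` (missing / not representable).
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt`, `ancestral_state` (one of `"ref"`, `"alt"`, `"unknown"`)
#'   and logical `multiallelic`.  Must be strictly increasing by
#'   (chrom, pos).
#' @param groups character vector, one of `"modern_carrier"`,
#'   `"modern_noncarrier"`, `"archaic"`, `"ancestral"` per haplotype.
#' @param sample_ids character vector mapping each haplotype row to its
#'   source sample (two rows per diploid sample share the value).
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, sites, groups, sample_ids = NULL) {
  if (!is.matrix(alleles)) alleles <- matrix(alleles, nrow = max(1L, NROW(alleles)))
  storage.mode(alleles) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "id", "ref", "alt", "ancestral_state", "multiallelic")
  for (col in setdiff(needed, names(sites))) {
    sites[[col]] <- switch(col,
      id = ".", ancestral_state = "unknown", multiallelic = FALSE,
      stop("sites is missing required column '", col, "'", call. = FALSE))
  }
  sites <- sites[needed]
  if (nrow(sites) != ncol(alleles))
    stop("ncol(alleles) != nrow(sites)", call. = FALSE)
  if (length(groups) != nrow(alleles))
    stop("length(groups) != nrow(alleles)", call. = FALSE)
  ok <- groups %in% c("modern_carrier", "modern_noncarrier", "archaic", "ancestral")
  if (!all(ok)) stop("unknown group label(s): ",
                     paste(unique(groups[!ok]), collapse = ", "), call. = FALSE)
  if (nrow(sites) > 1L) {
    o <- order(sites$chrom, sites$pos)
    if (any(o != seq_len(nrow(sites))) ||
        any(duplicated(sites[c("chrom", "pos")])))
      stop("sites must be strictly increasing by (chrom, pos)", call. = FALSE)
  }
  bad <- !(alleles %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("alleles must be 0, 1 or NA", call. = FALSE)
  if (is.null(rownames(alleles)))
    rownames(alleles) <- sprintf("hap%d", seq_len(nrow(alleles)))
  if (is.null(sample_ids)) sample_ids <- sub("_[12]$", "", rownames(alleles))
  structure(
    list(alleles = alleles, sites = sites, groups = as.character(groups),
         sample_ids = as.character(sample_ids)),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d sites\n",
              nrow(x$alleles), nrow(x$sites)))
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (nrow(x$sites))
    cat(sprintf("  span: %s:%d-%d\n", x$sites$chrom[1L],
                min(x$sites$pos), max(x$sites$pos)))
  invisible(x)
}

#' Number of haplotypes / sites in a panel
#' @param panel a [haplotype_panel()]
#' @return integer count
#' @export
n_haplotypes <- function(panel) nrow(panel$alleles)

#' @rdname n_haplotypes
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Subset a panel by site index or region
#'
#' Site order and coordinates are preserved; haplotype rows are untouched.
#'
#' @param panel a [haplotype_panel()]
#' @param sites integer/logical index into the panel's site list, or `NULL`
#' @param region optional `"chrom:start-end"` string (1-based inclusive)
#' @param haplotypes optional integer/logical/character index of rows
#' @return a [haplotype_panel()]
#' @export
subset_panel <- function(panel, sites = NULL, region = NULL, haplotypes = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  keep <- seq_len(n_sites(panel))
  if (!is.null(region)) {
    reg <- parse_region(region)
    keep <- keep[panel$sites$chrom[keep] == reg$chrom &
                 panel$sites$pos[keep] >= reg$start &
                 panel$sites$pos[keep] <= reg$end]
  }
  if (!is.null(sites)) {
    idx <- if (is.logical(sites)) which(sites) else as.integer(sites)
    keep <- intersect(keep, idx)
  }
  rows <- seq_len(n_haplotypes(panel))
  if (!is.null(haplotypes)) {
    rows <- if (is.character(haplotypes)) match(haplotypes, rownames(panel$alleles))
            else if (is.logical(haplotypes)) which(haplotypes) else as.integer(haplotypes)
    if (anyNA(rows)) stop("unknown haplotype selection", call. = FALSE)
  }
  haplotype_panel(panel$alleles[rows, keep, drop = FALSE],
                  panel$sites[keep, , drop = FALSE],
                  panel$groups[rows], panel$sample_ids[rows])
}

parse_region <- function(region) {
  if (is.list(region)) return(region)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L)
    stop("region must look like 'chr8:18150000-18350000'", call. = FALSE)
  list(chrom = m[2L], start = as.numeric(m[3L]), end = as.numeric(m[4L]))
}

#' Construct a genetic map
#'
#' A monotone physical-position to cumulative-centiMorgan lookup, queried by
#' linear interpolation.  No extrapolation: queries outside
#' `[min(pos), max(pos)]` are an error.
#'
#' @param pos ascending physical positions (bp)
#' @param cM nondecreasing cumulative map positions (centiMorgans)
#' @param chrom chromosome label (single string)
#' @return an object of class `genetic_map`
#' @export
genetic_map <- function(pos, cM, chrom = "chr8") {
  if (length(pos) != length(cM) || length(pos) < 2L)
    stop("need >= 2 aligned (pos, cM) rows", call. = FALSE)
  if (is.unsorted(pos, strictly = TRUE))
    stop("map positions must be strictly increasing", call. = FALSE)
  if (is.unsorted(cM))
    stop("cumulative cM must be nondecreasing", call. = FALSE)
  structure(list(chrom = chrom, pos = as.numeric(pos), cM = as.numeric(cM)),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %s: %d anchors, %.0f-%.0f bp, %.4f-%.4f cM\n",
              x$chrom, length(x$pos), min(x$pos), max(x$pos),
              min(x$cM), max(x$cM)))
  invisible(x)
}

#' Interpolate cumulative cM at physical positions
#' @param map a [genetic_map()]
#' @param pos positions (bp) within the map's range
#' @return cumulative cM at each position
#' @export
interpolate_cM <- function(map, pos) {
  stopifnot(inherits(map, "genetic_map"))
  if (any(pos < min(map$pos) | pos > max(map$pos)))
    stop("position outside genetic map range [", min(map$pos), ", ",
         max(map$pos), "]; extrapolation is not performed", call. = FALSE)
  approx(map$pos, map$cM, xout = pos, method = "linear", ties = "ordered")$y
}

#' Construct an accessibility mask
#'
#' Half-open, 0-based intervals (BED convention).  Overlapping or touching
#' intervals are merged so the stored set is non-overlapping.
#'
#' @param chrom,start,end aligned vectors of intervals `[start, end)`
#' @return an object of class `region_mask`
#' @export
region_mask <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("mask intervals need end > start", call. = FALSE)
  dt <- data.table(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end))
  setorder(dt, chrom, start, end)
  # merge overlapping or abutting intervals per chromosome
  dt[, grp := cumsum(start > shift(cummax(end), fill = -Inf)), by = chrom]
  out <- dt[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  out[, grp := NULL]
  structure(list(intervals = as.data.frame(out)), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d intervals, %.0f bp total\n",
              nrow(x$intervals), sum(x$intervals$end - x$intervals$start)))
  invisible(x)
}

#' Test whether 1-based positions fall inside a mask
#' @param mask a [region_mask()]
#' @param chrom chromosome label (recycled)
#' @param pos 1-based positions
#' @return logical vector
#' @export
in_mask <- function(mask, chrom, pos) {
  stopifnot(inherits(mask, "region_mask"))
  iv <- mask$intervals
  vapply(seq_along(pos), function(i) {
    ch <- if (length(chrom) == 1L) chrom else chrom[i]
    any(iv$chrom == ch & iv$start < pos[i] & pos[i] <= iv$end)
  }, logical(1L))
}
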