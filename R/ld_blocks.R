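#' Haplotypic r-squared between two sites
#'
#' The squared Pearson correlation of phased allele indicators — the
#' standard haplotypic linkage-disequilibrium statistic
#' r^2 = (p11 - pA pB)^2 / (pA qA pB qB).  Symmetric and invariant to
#' allele relabelling.  A monomorphic column has no defined correlation and
#' returns `NA` (never 0).
#'
#' @param hapA,hapB equal-length 0/1 allele vectors over the same haplotypes
#' @return r^2 in \[0, 1\], or `NA` if either column is monomorphic
#' @export
r_squared <- function(hapA, hapB) {
  if (length(hapA) != length(hapB))
    stop("allele columns differ in length", call. = FALSE)
  if (anyNA(hapA) || anyNA(hapB))
    stop("missing alleles; filter sites first", call. = FALSE)
  if (var(hapA) == 0 || var(hapB) == 0) return(NA_real_)
  cor(hapA, hapB)^2
}

#' Linkage-disequilibrium profile of a focal variant
#'
#' r^2 of the focal site against every other site within `max_window_bp`,
#' computed over the phased modern haplotypes (archaic and ancestral rows
#' are excluded: LD is a property of the modern panel).
#'
#' @param panel a missing-free [haplotype_panel()]
#' @param focal_pos physical position of the focal (proxy) variant
#' @param max_window_bp half-width of the search window around the focal
#' @return data.frame(pos, id, r2) including the focal site (r2 = 1)
#' @export
ld_profile <- function(panel, focal_pos, max_window_bp = 1e6) {
  stopifnot(inherits(panel, "haplotype_panel"))
  rows <- grepl("^modern", panel$groups)
  if (sum(rows) < 2L) stop("need >= 2 modern haplotypes", call. = FALSE)
  fi <- match(focal_pos, panel$sites$pos)
  if (is.na(fi)) stop("focal site ", focal_pos, " not in panel", call. = FALSE)
  X <- panel$alleles[rows, , drop = FALSE]
  f <- X[, fi]
  if (var(f) == 0)
    stop("focal site is monomorphic in the modern panel", call. = FALSE)
  win <- which(abs(panel$sites$pos - focal_pos) <= max_window_bp)
  r2 <- vapply(win, function(j) r_squared(f, X[, j]), numeric(1L))
  data.frame(pos = panel$sites$pos[win], id = panel$sites$id[win], r2 = r2)
}

#' Call an LD-defined haplotype block around a focal variant
#'
#' The block runs from the last upstream to the last downstream variant
#' whose r^2 with the focal variant strictly exceeds `threshold` — i.e. the
#' outermost qualifying variants within the search window, tolerating
#' internal dips below the threshold.  If no variant qualifies on a side,
#' that boundary is the focal site itself.
#'
#' @inheritParams ld_profile
#' @param threshold r^2 cutoff (strict inequality), default 0.8
#' @return an object of class `haplotype_block`: focal site row, boundary
#'   site rows, `span_bp`, the threshold and the full r^2 profile
#' @export
call_block <- function(panel, focal_pos, threshold = 0.8, max_window_bp = 1e6) {
  prof <- ld_profile(panel, focal_pos, max_window_bp)
  qual <- prof$pos[!is.na(prof$r2) & prof$r2 > threshold]
  qual <- unique(c(qual, focal_pos))
  up <- min(qual); down <- max(qual)
  site_row <- function(p) panel$sites[match(p, panel$sites$pos), , drop = FALSE]
  structure(list(focal = site_row(focal_pos),
                 upstream_boundary = site_row(up),
                 downstream_boundary = site_row(down),
                 span_bp = down - up, threshold = threshold,
                 profile = prof),
            class = "haplotype_block")
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("<haplotype_block> focal %s:%.0f (%s)\n", x$focal$chrom, x$focal$pos,
              x$focal$id))
  cat(sprintf("  %s:%.0f - %s:%.0f  span %s (r2 > %g)\n",
              x$upstream_boundary$chrom, x$upstream_boundary$pos,
              x$downstream_boundary$chrom, x$downstream_boundary$pos,
              format_kb(x$span_bp), x$threshold))
  invisible(x)
}

#' Physical span between block boundaries
#'
#' Either pass a `haplotype_block`, or the two boundary coordinates
#' directly.
#'
#' @param x a `haplotype_block`, or the upstream boundary position (bp)
#' @param downstream_pos downstream boundary position when `x` is numeric
#' @return span in bp
#' @export
block_span <- function(x, downstream_pos = NULL) {
  if (inherits(x, "haplotype_block")) return(x$span_bp)
  stopifnot(is.numeric(x), is.numeric(downstream_pos))
  downstream_pos - x
}

#' @rdname block_span
#' @param span_bp physical span in bp
#' @return `format_kb`: the span rendered to the nearest kb, e.g. `"89 kb"`
#' @export
format_kb <- function(span_bp) sprintf("%d kb", as.integer(round(span_bp / 1000)))

#' Genetic length of a haplotype block
#'
#' Cumulative cM is linearly interpolated at each boundary and differenced.
#' Boundaries outside the map range are an error (no extrapolation).
#'
#' @param block a `haplotype_block`, or numeric `c(start_bp, end_bp)`
#' @param map a [genetic_map()]
#' @return genetic length in cM
#' @export
block_genetic_length <- function(block, map) {
  bounds <- if (inherits(block, "haplotype_block"))
    c(block$upstream_boundary$pos, block$downstream_boundary$pos)
  else as.numeric(block)
  stopifnot(length(bounds) == 2L, bounds[2L] >= bounds[1L])
  cm <- interpolate_cM(map, bounds)
  cm[2L] - cm[1L]
}
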