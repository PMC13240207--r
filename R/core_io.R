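#' Read a phased multi-sample VCF into a haplotype panel
#'
#' Parses VCF 4.x text (uncompressed or gzipped).  Modern samples must be
#' phased (`a|b`); an unphased genotype in a modern sample is an error that
#' names the sample and site.  Samples listed in `archaic_samples` may be
#' unphased: their two genotype alleles are stored as two rows each, to be
#' collapsed to one pseudo-haplotype after archaic-heterozygous sites are
#' removed.  Multiallelic records are retained at read time and flagged in
#' `sites$multiallelic` (their non-ref alleles are stored as `NA`); they are
#' removed by [filter_sites()].  Any `.` allele (including half-calls such
#' as `.|0`) is treated as missing.  The ancestral state is taken from an
#' `AA=` INFO tag when present.
#'
#' @param path VCF file
#' @param region optional `"chrom:start-end"` restriction (1-based inclusive)
#' @param archaic_samples sample names to label `"archaic"`
#' @param carrier_samples sample names to label `"modern_carrier"`
#'   (haplotype-level carrier flags can also be set later)
#' @return a [haplotype_panel()]
#' @export
read_phased_vcf <- function(path, region = NULL, archaic_samples = character(),
                            carrier_samples = character()) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path, call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[hdr[1L]]), "\t")[[1L]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1L])]
  body <- body[!startsWith(body, "#")]
  if (!length(body)) {
    return(haplotype_panel(
      matrix(integer(), nrow = 2L * length(samples), ncol = 0L,
             dimnames = list(paste(rep(samples, each = 2L), 1:2, sep = "_"), NULL)),
      empty_sites(), vcf_groups(samples, archaic_samples, carrier_samples),
      rep(samples, each = 2L)))
  }
  dt <- fread(text = body, sep = "\t", header = FALSE, colClasses = "character")
  setnames(dt, seq_along(cols), cols)
  if (!is.null(region)) {
    reg <- parse_region(region)
    dt <- dt[CHROM == reg$chrom & as.numeric(POS) >= reg$start &
             as.numeric(POS) <= reg$end]
  }
  ns <- nrow(dt)
  multi <- if (ns) grepl(",", dt$ALT, fixed = TRUE) else logical(0)
  aa <- sub(".*(?:^|;)AA=([^;]*).*", "\\1", dt$INFO)
  aa[!grepl("AA=", dt$INFO)] <- ""
  alt1 <- sub(",.*", "", dt$ALT)
  anc <- ifelse(toupper(aa) == toupper(dt$REF), "ref",
         ifelse(toupper(aa) == toupper(alt1) & nzchar(aa), "alt", "unknown"))
  sites <- data.frame(chrom = dt$CHROM, pos = as.numeric(dt$POS), id = dt$ID,
                      ref = dt$REF, alt = alt1, ancestral_state = anc,
                      multiallelic = multi, stringsAsFactors = FALSE)
  alleles <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = ns)
  rownames(alleles) <- paste(rep(samples, each = 2L), 1:2, sep = "_")
  for (j in seq_along(samples)) {
    gt <- sub(":.*", "", dt[[samples[j]]])
    phased <- grepl("|", gt, fixed = TRUE)
    unph <- grepl("/", gt, fixed = TRUE)
    if (!(samples[j] %in% archaic_samples) && any(unph)) {
      k <- which(unph)[1L]
      stop(sprintf("unphased genotype '%s' for modern sample %s at %s:%s",
                   gt[k], samples[j], dt$CHROM[k], dt$POS[k]), call. = FALSE)
    }
    parts <- strsplit(gt, "[|/]")
    a1 <- vapply(parts, `[`, "", 1L)
    a2 <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
    code <- function(a) {
      v <- suppressWarnings(as.integer(a))
      v[!is.na(v) & v > 1L] <- NA_integer_  # non-primary alt: flagged multiallelic
      v
    }
    alleles[2L * j - 1L, ] <- code(a1)
    alleles[2L * j, ] <- code(a2)
  }
  haplotype_panel(alleles, sites,
                  vcf_groups(samples, archaic_samples, carrier_samples),
                  rep(samples, each = 2L))
}

vcf_groups <- function(samples, archaic_samples, carrier_samples) {
  g <- ifelse(samples %in% archaic_samples, "archaic",
       ifelse(samples %in% carrier_samples, "modern_carrier",
              "modern_noncarrier"))
  rep(g, each = 2L)
}

empty_sites <- function() {
  data.frame(chrom = character(), pos = numeric(), id = character(),
             ref = character(), alt = character(),
             ancestral_state = character(), multiallelic = logical(),
             stringsAsFactors = FALSE)
}

#' Write a haplotype panel as a phased VCF
#'
#' Modern samples are written `a|b`; archaic samples `a/b` (unphased).
#' Missing alleles become `.`.  The ancestral state, when known, is emitted
#' as an `AA=` INFO tag.  The companion reader is [read_phased_vcf()]; the
#' two round-trip losslessly for biallelic panels.
#'
#' @param panel a [haplotype_panel()]
#' @param path output file
#' @param header_extra optional character vector of extra `##` header lines
#'   (used by the simulator to record its seed)
#' @return `path`, invisibly
#' @export
write_panel_vcf <- function(panel, path, header_extra = character()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  samples <- unique(panel$sample_ids[panel$groups != "ancestral"])
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           header_extra,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  s <- panel$sites
  aa <- ifelse(s$ancestral_state == "ref", s$ref,
        ifelse(s$ancestral_state == "alt", s$alt, NA))
  info <- ifelse(is.na(aa), ".", paste0("AA=", aa))
  rows <- character(nrow(s))
  gtchr <- function(v) ifelse(is.na(v), ".", as.character(v))
  cells <- matrix("", nrow = nrow(s), ncol = length(samples))
  for (j in seq_along(samples)) {
    idx <- which(panel$sample_ids == samples[j] & panel$groups != "ancestral")
    sep <- if (panel$groups[idx[1L]] == "archaic") "/" else "|"
    a1 <- panel$alleles[idx[1L], ]
    a2 <- if (length(idx) > 1L) panel$alleles[idx[2L], ] else a1
    cells[, j] <- paste0(gtchr(a1), sep, gtchr(a2))
  }
  body <- if (nrow(s)) paste(s$chrom, format(s$pos, scientific = FALSE, trim = TRUE),
                             s$id, s$ref, s$alt, ".", "PASS", info, "GT",
                             apply(cells, 1L, paste, collapse = "\t"),
                             sep = "\t") else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter panel sites to the analysis-ready set
#'
#' Applies, in one pass, the merged-panel site filters: drop sites outside
#' the accessibility mask, multiallelic sites, sites with missing data for
#' any individual (strict), sites not segregating in the merged panel, and
#' (optionally) sites at which any archaic genome is heterozygous.  Site
#' order is preserved and the operation is idempotent.
#'
#' @param panel a [haplotype_panel()]
#' @param mask optional [region_mask()]
#' @param drop_archaic_hets drop sites heterozygous in any archaic
#'   (required before collapsing archaics to single pseudo-haplotypes)
#' @return the filtered [haplotype_panel()] (possibly with zero sites)
#' @export
filter_sites <- function(panel, mask = NULL, drop_archaic_hets = TRUE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n_sites(panel) == 0L) return(panel)
  keep <- !panel$sites$multiallelic
  if (!is.null(mask))
    keep <- keep & in_mask(mask, panel$sites$chrom, panel$sites$pos)
  rows <- panel$groups != "ancestral"
  keep <- keep & colSums(is.na(panel$alleles[rows, , drop = FALSE])) == 0L
  if (drop_archaic_hets)
    keep <- keep & !archaic_het_sites(panel)
  cs <- colSums(panel$alleles[rows, , drop = FALSE], na.rm = TRUE)
  keep <- keep & cs > 0L & cs < sum(rows)  # segregating in the merged panel
  subset_panel(panel, sites = which(keep))
}

# TRUE at sites where the two genotype rows of any archaic sample differ
archaic_het_sites <- function(panel) {
  out <- rep(FALSE, n_sites(panel))
  arch <- unique(panel$sample_ids[panel$groups == "archaic"])
  for (s in arch) {
    idx <- which(panel$sample_ids == s)
    if (length(idx) == 2L) {
      a <- panel$alleles[idx[1L], ]
      b <- panel$alleles[idx[2L], ]
      out <- out | (!is.na(a) & !is.na(b) & a != b) | xor(is.na(a), is.na(b))
    }
  }
  out
}

#' Collapse archaic genotype rows to single pseudo-haplotypes
#'
#' After archaic-heterozygous sites have been removed the two genotype rows
#' of each archaic sample are identical; this keeps one row per archaic,
#' named by the sample, so each archaic is represented by a single
#' chromosome in affinity and tree analyses.
#'
#' @param panel a [haplotype_panel()] already passed through
#'   [filter_sites()] with `drop_archaic_hets = TRUE`
#' @return a [haplotype_panel()]
#' @export
collapse_archaics <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (any(archaic_het_sites(panel)))
    stop("archaic-heterozygous sites present; run filter_sites() first",
         call. = FALSE)
  drop <- panel$groups == "archaic" & duplicated(panel$sample_ids)
  out <- subset_panel(panel, haplotypes = which(!drop))
  arch <- out$groups == "archaic"
  rownames(out$alleles)[arch] <- out$sample_ids[arch]
  out
}

#' Append the inferred ancestral sequence as a haplotype
#'
#' Sites with unknown ancestral state cannot be polarised and are dropped
#' before the ancestral row (group `"ancestral"`, id `"ancestral"`) is
#' appended; it is the rooting outgroup for [nj_tree()].
#'
#' @param panel a missing-free [haplotype_panel()]
#' @return a [haplotype_panel()] restricted to ancestrally-informative sites
#' @export
add_ancestral_haplotype <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  keep <- panel$sites$ancestral_state != "unknown"
  p <- subset_panel(panel, sites = which(keep))
  anc <- ifelse(p$sites$ancestral_state == "ref", 0L, 1L)
  alleles <- rbind(p$alleles, ancestral = anc)
  haplotype_panel(alleles, p$sites, c(p$groups, "ancestral"),
                  c(p$sample_ids, "ancestral"))
}

#' Export panel haplotypes as aligned sequences
#'
#' One record per haplotype; record `i` position `j` is the ref or alt base
#' of site `j` according to the allele matrix.  The panel must be
#' missing-free (run [filter_sites()] first).
#'
#' @param panel a [haplotype_panel()]
#' @param path optional FASTA output file
#' @return named character vector of sequences, invisibly when `path` given
#' @export
haplotypes_to_fasta <- function(panel, path = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (anyNA(panel$alleles))
    stop("panel has missing alleles; run filter_sites() first", call. = FALSE)
  bases <- rbind(panel$sites$ref, panel$sites$alt)
  seqs <- apply(panel$alleles, 1L, function(h) {
    if (!length(h)) "" else paste(bases[cbind(h + 1L, seq_along(h))], collapse = "")
  })
  names(seqs) <- rownames(panel$alleles)
  if (!is.null(path)) {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
    return(invisible(seqs))
  }
  seqs
}

#' Read a genetic map from TSV
#'
#' Expects columns `chrom`, `pos`, `cM` (cumulative centiMorgans; the
#' header name may also be `cumulative_cM`).  A decreasing cM column is an
#' error.
#'
#' @param path TSV file
#' @return a [genetic_map()]
#' @export
read_genetic_map <- function(path) {
  dt <- fread(path)
  cmcol <- intersect(c("cM", "cumulative_cM"), names(dt))
  if (!all(c("chrom", "pos") %in% names(dt)) || !length(cmcol))
    stop("genetic map needs columns chrom, pos, cM", call. = FALSE)
  genetic_map(dt$pos, dt[[cmcol[1L]]], chrom = dt$chrom[1L])
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()]
#' @export
write_genetic_map <- function(map, path) {
  fwrite(data.table(chrom = map$chrom, pos = map$pos, cM = map$cM),
         path, sep = "\t")
  invisible(path)
}

#' Read an accessibility mask from BED
#'
#' Standard 0-based half-open BED; touching or overlapping intervals are
#' merged on read.
#'
#' @param path BED file (>= 3 columns, no header)
#' @return a [region_mask()]
#' @export
read_mask <- function(path) {
  dt <- fread(path, header = FALSE)
  if (ncol(dt) < 3L) stop("BED mask needs >= 3 columns", call. = FALSE)
  region_mask(dt[[1L]], dt[[2L]], dt[[3L]])
}

#' @rdname read_mask
#' @param mask a [region_mask()]
#' @export
write_mask <- function(mask, path) {
  fwrite(as.data.table(mask$intervals), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read archaic fragment genetic lengths from TSV
#'
#' One genetic length (cM) per row; a single header line is tolerated.
#'
#' @param path TSV file
#' @return numeric vector of lengths (cM)
#' @export
read_fragments <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1L]][1L])))
  dt <- fread(path, header = has_header)
  x <- as.numeric(dt[[1L]])
  if (anyNA(x) || any(x < 0)) stop("fragment lengths must be nonnegative numbers",
                                   call. = FALSE)
  x
}

#' @rdname read_fragments
#' @param lengths_cM numeric vector of fragment lengths (cM)
#' @export
write_fragments <- function(lengths_cM, path) {
  fwrite(data.table(length_cM = lengths_cM), path, sep = "\t")
  invisible(path)
}
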