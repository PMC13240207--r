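#' Pairwise differences between two haplotypes
#'
#' Hamming count over the retained site set.
#'
#' @param hapA,hapB equal-length, missing-free 0/1 allele vectors
#' @return integer count of differing sites
#' @export
pairwise_differences <- function(hapA, hapB) {
  if (length(hapA) != length(hapB))
    stop("haplotypes differ in length", call. = FALSE)
  if (anyNA(hapA) || anyNA(hapB))
    stop("missing alleles; filter sites first", call. = FALSE)
  sum(hapA != hapB)
}

#' Pairwise-difference matrix over all haplotypes
#'
#' @param x a missing-free [haplotype_panel()] or 0/1 matrix
#'   (rows = haplotypes)
#' @param per_site divide counts by the number of sites
#'   (differences per site, the usual tree branch-length scale)
#' @return symmetric numeric matrix with zero diagonal
#' @export
distance_matrix <- function(x, per_site = FALSE) {
  X <- if (inherits(x, "haplotype_panel")) x$alleles else x
  if (anyNA(X)) stop("missing alleles; filter sites first", call. = FALSE)
  storage.mode(X) <- "double"
  D <- X %*% t(1 - X)
  D <- D + t(D)
  dimnames(D) <- list(rownames(X), rownames(X))
  if (per_site) D / max(1L, ncol(X)) else D
}

#' Deduplicate identical haplotypes
#'
#' Keeps the first occurrence of each distinct allele vector and reports
#' how many haplotypes each unique representative stands for.
#'
#' @param panel a missing-free [haplotype_panel()]
#' @return list: `panel` (unique haplotypes), `multiplicity` (named integer
#'   vector over representatives, summing to the original haplotype
#'   count), `members` (list mapping representative to original ids)
#' @export
dedup_haplotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (anyNA(panel$alleles)) stop("missing alleles; filter sites first",
                                 call. = FALSE)
  key <- apply(panel$alleles, 1L, paste, collapse = "")
  first <- !duplicated(key)
  rep_of <- rownames(panel$alleles)[first][match(key, key[first])]
  members <- split(rownames(panel$alleles), rep_of)
  mult <- vapply(members, length, integer(1L))
  reps <- rownames(panel$alleles)[first]
  list(panel = subset_panel(panel, haplotypes = which(first)),
       multiplicity = mult[reps], members = members[reps])
}

#' Nearest archaic genome to a query haplotype
#'
#' Argmin of pairwise differences over the archaic pseudo-haplotypes; exact
#' ties are reported as a set, not broken arbitrarily.
#'
#' @param query_hap missing-free 0/1 allele vector
#' @param archaic_haps matrix of archaic pseudo-haplotypes (rows), or a
#'   [haplotype_panel()] whose `"archaic"` rows are used
#' @return list: `label` (character vector, the tie set), `count` (the
#'   minimal difference count), `counts` (all counts, named)
#' @export
nearest_archaic <- function(query_hap, archaic_haps) {
  A <- if (inherits(archaic_haps, "haplotype_panel"))
    archaic_haps$alleles[archaic_haps$groups == "archaic", , drop = FALSE]
  else archaic_haps
  if (!is.matrix(A)) A <- matrix(A, nrow = 1L, dimnames = list("archaic1"))
  if (nrow(A) < 1L) stop("need at least one archaic haplotype", call. = FALSE)
  counts <- apply(A, 1L, pairwise_differences, hapB = query_hap)
  names(counts) <- rownames(A)
  m <- min(counts)
  list(label = names(counts)[counts == m], count = m, counts = counts)
}

#' Per-site allele sharing between two modern groups and an archaic
#'
#' For each retained site, records whether the archaic allele matches the
#' (strict-majority) allele of group A and of group B.  A group tied 50/50
#' at a site has no majority allele; such sites are emitted with
#' `NA` sharing flags and `tie_*` set, a third category rather than an
#' arbitrary break.
#'
#' @param panel a missing-free [haplotype_panel()]
#' @param groupA,groupB disjoint, nonempty haplotype id vectors (or the
#'   group labels `"modern_carrier"` / `"modern_noncarrier"`)
#' @param archaic haplotype id of the archaic row to compare against
#' @return data.frame(pos, id, archaic_allele, alleleA, alleleB,
#'   shared_with_A, shared_with_B, tie_A, tie_B)
#' @export
allele_sharing_track <- function(panel, groupA, groupB, archaic) {
  stopifnot(inherits(panel, "haplotype_panel"))
  resolve <- function(g) {
    if (length(g) == 1L && g %in% panel$groups) which(panel$groups == g)
    else match(g, rownames(panel$alleles))
  }
  ia <- resolve(groupA); ib <- resolve(groupB)
  if (!length(ia) || anyNA(ia)) stop("group A is empty or unknown", call. = FALSE)
  if (!length(ib) || anyNA(ib)) stop("group B is empty or unknown", call. = FALSE)
  if (length(intersect(ia, ib))) stop("groups must be disjoint", call. = FALSE)
  iq <- match(archaic, rownames(panel$alleles))
  if (is.na(iq)) stop("unknown archaic haplotype '", archaic, "'", call. = FALSE)
  if (anyNA(panel$alleles[c(ia, ib, iq), ]))
    stop("missing alleles; filter sites first", call. = FALSE)
  majority <- function(idx) {
    ones <- colSums(panel$alleles[idx, , drop = FALSE])
    n <- length(idx)
    ifelse(2 * ones > n, 1L, ifelse(2 * ones < n, 0L, NA_integer_))
  }
  aA <- majority(ia); aB <- majority(ib)
  arc <- panel$alleles[iq, ]
  data.frame(pos = panel$sites$pos, id = panel$sites$id,
             archaic_allele = arc, alleleA = aA, alleleB = aB,
             shared_with_A = aA == arc, shared_with_B = aB == arc,
             tie_A = is.na(aA), tie_B = is.na(aB),
             row.names = NULL)
}

#' Neighbor-joining tree with site-resampling bootstrap
#'
#' Builds the pairwise-difference matrix (per retained site), runs neighbor
#' joining, clamps negative branch lengths to zero, roots on the outgroup
#' and, when `bootstrap > 0`, attaches per-internal-edge support computed
#' by rerunning NJ on `bootstrap` site-resampled panels.  With exactly
#' three taxa the closed-form three-point solution is used
#' (x_i = (d_ij + d_ik - d_jk) / 2).
#'
#' @param x a missing-free [haplotype_panel()] or 0/1 allele matrix
#'   (rows = haplotypes); a precomputed distance matrix is also accepted,
#'   but then `bootstrap` must be 0 (site resampling needs the alleles)
#' @param outgroup row label to root on (e.g. `"ancestral"`), or `NULL`
#'   for an unrooted tree
#' @param bootstrap number of site-resampling replicates (0 = none)
#' @param seed RNG seed for the bootstrap
#' @param per_site report branch lengths as differences per site
#'   (default) rather than raw counts
#' @return an object of class `tree_result`: `tree` (an `ape::phylo` with
#'   `node.label` holding support fractions when bootstrapped), `support`
#'   (numeric vector over internal nodes, or `NULL`), `n_sites`, `B`
#' @export
nj_tree <- function(x, outgroup = NULL, bootstrap = 0L, seed = 1L,
                    per_site = TRUE) {
  is_dist <- is.matrix(x) && nrow(x) == ncol(x) &&
    !is.null(rownames(x)) && identical(rownames(x), colnames(x)) &&
    all(abs(diag(x)) < 1e-12)
  if (is_dist) {
    if (bootstrap > 0)
      stop("bootstrap needs the allele matrix, not a distance matrix",
           call. = FALSE)
    D <- x
    n_sites <- NA_integer_
  } else {
    X <- if (inherits(x, "haplotype_panel")) x$alleles else x
    n_sites <- ncol(X)
    D <- distance_matrix(X, per_site = per_site)
  }
  if (nrow(D) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (!is.null(outgroup) && !outgroup %in% rownames(D))
    stop("outgroup '", outgroup, "' not among taxa", call. = FALSE)
  tree <- nj_build(D, outgroup)
  support <- NULL
  if (bootstrap > 0) {
    boots <- with_seed(seed, lapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(n_sites, n_sites, replace = TRUE)
      nj_build(distance_matrix(X[, idx, drop = FALSE], per_site = per_site),
               outgroup)
    }))
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    support <- ifelse(is.na(counts), 0, counts) / bootstrap
    tree$node.label <- formatC(support, format = "g")
  }
  structure(list(tree = tree, support = support, n_sites = n_sites,
                 B = as.integer(bootstrap), outgroup = outgroup),
            class = "tree_result")
}

# NJ topology + branch lengths, negative lengths clamped, optional rooting
nj_build <- function(D, outgroup) {
  tree <- if (nrow(D) == 3L) three_point_tree(D) else ape::nj(as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  tree
}

three_point_tree <- function(D) {
  lab <- rownames(D)
  x <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
         (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
         (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  tree <- list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2L, byrow = TRUE),
               edge.length = x, tip.label = lab, Nnode = 1L)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' @export
print.tree_result <- function(x, ...) {
  cat(sprintf("<tree_result> %d tips, %s sites, bootstrap B = %d\n",
              length(x$tree$tip.label),
              ifelse(is.na(x$n_sites), "?", x$n_sites), x$B))
  if (!is.null(x$outgroup)) cat("  rooted on", x$outgroup, "\n")
  invisible(x)
}

#' Bootstrap support for the monophyly of a taxon set
#'
#' Fraction of site-resampled NJ trees in which `taxa` form a clade
#' (evaluated on the unrooted topology against all remaining taxa).
#'
#' @param x a missing-free [haplotype_panel()] or 0/1 allele matrix
#' @param taxa row labels of the putative clade
#' @param bootstrap replicates
#' @param seed RNG seed
#' @param outgroup optional taxon to root each replicate on before testing
#' @return list: `support` (fraction), `observed` (is the clade in the
#'   point-estimate tree?)
#' @export
clade_support <- function(x, taxa, bootstrap = 100L, seed = 1L,
                          outgroup = NULL) {
  X <- if (inherits(x, "haplotype_panel")) x$alleles else x
  stopifnot(is.matrix(X), all(taxa %in% rownames(X)))
  mono <- function(tr) ape::is.monophyletic(tr, taxa, reroot = is.null(outgroup))
  main <- nj_build(distance_matrix(X, per_site = TRUE), outgroup)
  hits <- with_seed(seed, vapply(seq_len(bootstrap), function(b) {
    idx <- sample.int(ncol(X), ncol(X), replace = TRUE)
    mono(nj_build(distance_matrix(X[, idx, drop = FALSE], per_site = TRUE),
                  outgroup))
  }, logical(1L)))
  list(support = mean(hits), observed = mono(main))
}
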