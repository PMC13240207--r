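# Independent brute-force oracles.  These deliberately take different
# computational routes from the package implementations they check.

# r^2 via the classical LD coefficient D = pAB - pA pB, not via cor()
oracle_r2 <- function(a, b) {
  n <- length(a)
  pA <- sum(a) / n
  pB <- sum(b) / n
  pAB <- sum(a == 1 & b == 1) / n
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Hamming distance via an explicit loop
oracle_pairdiff <- function(a, b) {
  d <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) d <- d + 1L
  d
}

# Tajima's D from scratch: pi as the mean over all haplotype pairs of the
# loop-based Hamming distance; constants re-derived inline
oracle_tajima <- function(X) {
  n <- nrow(X)
  seg <- apply(X, 2L, function(col) length(unique(col)) == 2L)
  S <- sum(seg)
  pairs <- utils::combn(n, 2L)
  pi <- mean(apply(pairs, 2L, function(p) oracle_pairdiff(X[p[1L], ], X[p[2L], ])))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  if (S == 0) return(NA_real_)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# ordinary least-squares slope via the normal equations
oracle_ols_slope <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1L], slope = beta[2L])
}

# minimal panel builder for hand-made fixtures
make_panel <- function(alleles, pos = NULL, groups = NULL, chrom = "chr1",
                       anc = NULL, multi = NULL, ids = NULL) {
  alleles <- as.matrix(alleles)
  S <- ncol(alleles)
  if (is.null(pos)) pos <- seq_len(S) * 100
  if (is.null(groups)) groups <- rep("modern_noncarrier", nrow(alleles))
  sites <- data.frame(chrom = chrom, pos = pos,
                      id = sprintf("s%d", seq_len(S)),
                      ref = rep("A", S), alt = rep("G", S),
                      ancestral_state = anc %||% rep("ref", S),
                      multiallelic = multi %||% rep(FALSE, S))
  if (!is.null(ids)) rownames(alleles) <- ids
  haplotype_panel(alleles, sites, groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random polymorphic 0/1 matrix (base-R only; independent of simulate_panel)
random_panel_matrix <- function(n, S, p = NULL) {
  X <- matrix(0L, n, S)
  for (j in seq_len(S)) {
    k <- sample(n - 1L, 1L)
    X[sample(n, k), j] <- 1L
  }
  rownames(X) <- sprintf("h%d", seq_len(n))
  X
}

# tiny phased VCF writer for reader tests
write_toy_vcf <- function(path, rows, samples = c("s1", "s2"),
                          extra_header = character()) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}
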