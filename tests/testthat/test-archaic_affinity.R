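test_that("pairwise_differences is an exact Hamming count", {
  expect_equal(pairwise_differences(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(pairwise_differences(rep(0, 75), rep(1, 75)), 75)
  set.seed(77)
  a <- sample(0:1, 100, replace = TRUE)
  b <- sample(0:1, 100, replace = TRUE)
  expect_equal(pairwise_differences(a, b), oracle_pairdiff(a, b))
  expect_error(pairwise_differences(c(0, 1), c(0, 1, 1)), "length")
  expect_error(pairwise_differences(c(0, NA), c(0, 1)), "missing")
})

test_that("distance_matrix agrees with the pairwise loop", {
  set.seed(31)
  X <- random_panel_matrix(8, 40)
  D <- distance_matrix(X)
  for (i in 1:8) for (j in 1:8)
    expect_equal(D[i, j], oracle_pairdiff(X[i, ], X[j, ]))
  expect_equal(unname(diag(D)), rep(0, 8))
  expect_equal(distance_matrix(X, per_site = TRUE), D / 40)
})

test_that("dedup_haplotypes keeps first occurrences with multiplicities", {
  X <- rbind(h1 = c(0L, 1L), h2 = c(0L, 1L), h3 = c(1L, 1L), h4 = c(0L, 0L))
  d <- dedup_haplotypes(make_panel(X))
  expect_equal(n_haplotypes(d$panel), 3L)
  expect_equal(unname(d$multiplicity), c(2L, 1L, 1L))
  expect_equal(sum(d$multiplicity), 4L)
  expect_equal(d$members$h1, c("h1", "h2"))

  all_distinct <- make_panel(rbind(h1 = c(0L, 1L), h2 = c(1L, 0L)))
  expect_equal(n_haplotypes(dedup_haplotypes(all_distinct)$panel), 2L)

  same <- make_panel(matrix(1L, nrow = 10, ncol = 2))
  ds <- dedup_haplotypes(same)
  expect_equal(n_haplotypes(ds$panel), 1L)
  expect_equal(unname(ds$multiplicity), 10L)
})

test_that("nearest_archaic reports argmin and full tie sets", {
  A <- rbind(v1 = c(0L, 0L, 1L, 1L), v2 = c(1L, 1L, 1L, 1L))
  r <- nearest_archaic(c(0L, 0L, 1L, 1L), A)
  expect_equal(r$label, "v1")
  expect_equal(r$count, 0)
  expect_equal(unname(r$counts), c(0, 2))
  # symmetric construction: two equidistant archaics
  tie <- nearest_archaic(c(0L, 0L), rbind(x = c(1L, 0L), y = c(0L, 1L)))
  expect_setequal(tie$label, c("x", "y"))
})

test_that("allele sharing uses strict majorities and flags ties", {
  X <- rbind(c1 = c(1L, 0L, 1L), c2 = c(1L, 0L, 0L), c3 = c(1L, 1L, 1L),
             n1 = c(0L, 1L, 0L), n2 = c(0L, 1L, 1L),
             a1 = c(1L, 0L, 1L))
  p <- make_panel(X, groups = c(rep("modern_carrier", 3),
                                rep("modern_noncarrier", 2), "archaic"))
  tr <- allele_sharing_track(p, "modern_carrier", "modern_noncarrier", "a1")
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$shared_with_A, c(TRUE, TRUE, TRUE))
  expect_equal(tr$shared_with_B, c(FALSE, FALSE, NA))  # site 3 ties in B
  expect_equal(tr$tie_B, c(FALSE, FALSE, TRUE))
  # archaic identical to group A everywhere -> all shared with A
  expect_true(all(tr$shared_with_A))
  # single-site panel where both groups carry the archaic allele
  p1 <- make_panel(rbind(c1 = 1L, n1 = 1L, a1 = 1L),
                   groups = c("modern_carrier", "modern_noncarrier", "archaic"))
  tr1 <- allele_sharing_track(p1, "c1", "n1", "a1")
  expect_true(tr1$shared_with_A && tr1$shared_with_B)
  expect_error(allele_sharing_track(p, character(), "n1", "a1"), "empty")
  expect_error(allele_sharing_track(p, "c1", "c1", "a1"), "disjoint")
})

test_that("sharing with carriers is enriched inside the planted tract", {
  sim <- simulate_panel(sim_config(seed = 33))
  f <- collapse_archaics(filter_sites(sim$panel, sim$mask))
  tr <- allele_sharing_track(f, "modern_carrier", "modern_noncarrier", "arch1")
  inside <- tr$pos >= sim$truth$tract_start & tr$pos <= sim$truth$tract_end
  rate_in <- mean(tr$shared_with_A[inside], na.rm = TRUE)
  rate_out <- mean(tr$shared_with_A[!inside], na.rm = TRUE)
  expect_gt(rate_in, rate_out)
})

test_that("three-taxon trees use the closed-form three-point solution", {
  D <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)$tree
  tip_edge <- function(t, lab) t$edge.length[t$edge[, 2L] == match(lab, t$tip.label)]
  expect_equal(tip_edge(tr, "A"), 2)
  expect_equal(tip_edge(tr, "B"), 3)
  expect_equal(tip_edge(tr, "C"), 5)
  expect_error(nj_tree(D[1:2, 1:2]), "3 taxa")
})

test_that("neighbor joining is exact on an additive four-taxon matrix", {
  # tree ((A:2,B:3):1,(C:4,D:5)) -> additive distances
  lab <- c("A", "B", "C", "D")
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4L, dimnames = list(lab, lab))
  tr <- nj_tree(D)$tree
  expect_equal(ape::cophenetic.phylo(tr)[lab, lab], D)   # exact lengths
  expect_true(ape::is.monophyletic(tr, c("A", "B")))      # exact topology
  # label permutation invariance
  perm <- c("C", "A", "D", "B")
  tr2 <- nj_tree(D[perm, perm])$tree
  expect_equal(ape::cophenetic.phylo(tr2)[lab, lab], D)
})

test_that("identical taxa form a zero-length cherry and bootstrap is seeded", {
  X <- rbind(u = c(0L, 0L, 1L, 1L), v = c(0L, 0L, 1L, 1L),
             w = c(1L, 1L, 0L, 0L), anc = c(0L, 0L, 0L, 0L))
  r <- nj_tree(X, outgroup = "anc")
  tr <- r$tree
  iu <- match("u", tr$tip.label); iv <- match("v", tr$tip.label)
  expect_equal(ape::cophenetic.phylo(tr)["u", "v"], 0)
  b1 <- nj_tree(X, outgroup = "anc", bootstrap = 25, seed = 4)
  b2 <- nj_tree(X, outgroup = "anc", bootstrap = 25, seed = 4)
  expect_identical(b1$support, b2$support)
  expect_error(nj_tree(distance_matrix(X), bootstrap = 10), "allele matrix")
})
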