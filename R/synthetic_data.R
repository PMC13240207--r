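#' Simulation configuration
#'
#' Defaults describe the world the analysis assumes: a ~1 Mb neutral modern
#' panel into which a single archaic-derived tract was introduced about
#' 2,000 generations ago, alongside three high-coverage archaic
#' pseudo-genomes.  Densities are in segregating sites per kb of the modern
#' panel; archaic-lineage divergence scales off the same density.
#'
#' @param n_modern_haplotypes phased modern haplotypes (2 per sample)
#' @param n_archaic_genomes unphased archaic genomes
#' @param region_length region size in bp
#' @param chrom chromosome label
#' @param mutation_density modern segregating sites per kb
#' @param divergence_scale archaic-lineage shared private-derived site
#'   density, as a multiple of `mutation_density`
#' @param archaic_private_density per-archaic private hom-derived sites/kb
#' @param archaic_het_density per-archaic heterozygous (uncallable) sites/kb
#' @param admixture_generations generations since archaic gene flow (g);
#'   each side of the planted tract is Exponential with mean 100/g cM
#' @param recombination_rate uniform map rate, cM per Mb
#' @param carrier_fraction fraction of modern haplotypes carrying the tract
#' @param ancestral_known_frac fraction of sites with an ancestral-state call
#' @param seed integer RNG seed; identical seeds give bit-identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_modern_haplotypes = 100L, n_archaic_genomes = 3L,
                       region_length = 1e6, chrom = "chr8",
                       mutation_density = 0.8, divergence_scale = 1.0,
                       archaic_private_density = 0.05,
                       archaic_het_density = 0.05,
                       admixture_generations = 2000,
                       recombination_rate = 1.0,
                       carrier_fraction = 0.05,
                       ancestral_known_frac = 0.9,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_modern_haplotypes >= 4, cfg$n_archaic_genomes >= 1,
            cfg$region_length > 0, cfg$mutation_density > 0,
            cfg$divergence_scale >= 0, cfg$admixture_generations > 0,
            cfg$recombination_rate > 0,
            cfg$carrier_fraction >= 0, cfg$carrier_fraction <= 1,
            cfg$ancestral_known_frac >= 0, cfg$ancestral_known_frac <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a phased panel with a planted introgressed tract
#'
#' A mosaic mutation-drop model, not a full coalescent: modern background
#' sites are independent with derived counts drawn from the neutral site
#' frequency spectrum (P(i) proportional to 1/i), which preserves the
#' neutral expectation E\[pi\] = E\[S\]/a1 that Tajima's D contrasts;
#' archaic genomes carry a shared pool of private derived alleles plus
#' per-genome private and heterozygous sites; carrier haplotypes copy the
#' first archaic genome inside a tract centred on the region midpoint whose
#' per-side genetic length is Exponential(mean 100/g cM) — the standard
#' recombination clock g generations after admixture — and are ordinary
#' modern haplotypes outside it.
#'
#' @param config a [sim_config()]
#' @return list with elements `panel` ([haplotype_panel()]), `map`
#'   ([genetic_map()]), `mask` ([region_mask()]), `truth` (list: carrier
#'   haplotype ids, tract interval, tract genetic length in cM, source
#'   archaic label) and `config`
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(cfg) {
  L <- cfg$region_length
  nm <- as.integer(cfg$n_modern_haplotypes)
  na <- as.integer(cfg$n_archaic_genomes)
  kb <- L / 1000

  n_carrier <- round(cfg$carrier_fraction * nm)
  if (n_carrier > 0 &&
      cfg$divergence_scale * cfg$mutation_density + cfg$archaic_private_density <= 0)
    stop("carrier_fraction > 0 requires archaic variants (divergence_scale or ",
         "archaic_private_density must be positive)", call. = FALSE)

  draw_pos <- function(density) {
    n <- rpois(1L, density * kb)
    sort(sample.int(L, n))
  }
  pos_mod <- draw_pos(cfg$mutation_density)
  pos_arch <- draw_pos(cfg$divergence_scale * cfg$mutation_density)
  pos_priv <- lapply(seq_len(na), function(k) draw_pos(cfg$archaic_private_density))
  pos_het <- lapply(seq_len(na), function(k) draw_pos(cfg$archaic_het_density))

  pos_all <- c(pos_mod, pos_arch, unlist(pos_priv), unlist(pos_het))
  kind <- c(rep("mod", length(pos_mod)), rep("arch", length(pos_arch)),
            rep(sprintf("priv%d", seq_len(na)), lengths(pos_priv)),
            rep(sprintf("het%d", seq_len(na)), lengths(pos_het)))
  dup <- duplicated(pos_all)            # collisions: keep first class drawn
  pos_all <- pos_all[!dup]; kind <- kind[!dup]
  o <- order(pos_all); pos_all <- pos_all[o]; kind <- kind[o]
  S <- length(pos_all)

  # rows: modern haplotypes, then 2 genotype rows per archaic
  H <- nm + 2L * na
  alleles <- matrix(0L, nrow = H, ncol = S)
  rownames(alleles) <- c(sprintf("mod%d_%d", rep(seq_len(nm %/% 2L), each = 2L), 1:2),
                         sprintf("arch%d_%d", rep(seq_len(na), each = 2L), 1:2))
  arow <- function(k) nm + c(2L * k - 1L, 2L * k)

  # modern background: neutral SFS, independent sites
  imod <- which(kind == "mod")
  if (length(imod)) {
    counts <- sample(nm - 1L, length(imod), replace = TRUE,
                     prob = 1 / seq_len(nm - 1L))
    for (t in seq_along(imod))
      alleles[sample.int(nm, counts[t]), imod[t]] <- 1L
  }
  # archaic shared derived pool: hom in every archaic
  iarch <- which(kind == "arch")
  for (k in seq_len(na)) alleles[arow(k), iarch] <- 1L
  # archaic private hom-derived and heterozygous sites
  for (k in seq_len(na)) {
    alleles[arow(k), which(kind == sprintf("priv%d", k))] <- 1L
    alleles[arow(k)[2L], which(kind == sprintf("het%d", k))] <- 1L
  }

  # planted tract: per-side Exponential(100/g) cM, uniform map
  rate_cM_per_bp <- cfg$recombination_rate / 1e6
  truth <- NULL
  if (n_carrier > 0) {
    side_cM <- rexp(2L, rate = cfg$admixture_generations / 100)
    side_bp <- side_cM / rate_cM_per_bp
    centre <- L / 2
    tract <- c(max(1, floor(centre - side_bp[1L])),
               min(L, ceiling(centre + side_bp[2L])))
    carriers <- sort(sample.int(nm, n_carrier))
    in_tract <- pos_all >= tract[1L] & pos_all <= tract[2L]
    src <- alleles[arow(1L)[1L], ]     # source archaic pseudo-haplotype
    alleles[carriers, in_tract] <- rep(src[in_tract], each = n_carrier)
    truth <- list(carrier_ids = rownames(alleles)[carriers],
                  tract_start = tract[1L], tract_end = tract[2L],
                  tract_cM = (tract[2L] - tract[1L]) * rate_cM_per_bp,
                  source_archaic = "arch1")
  }

  # site metadata: allele 0 is ancestral by construction
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  anc <- ifelse(runif(S) < cfg$ancestral_known_frac, "ref", "unknown")
  sites <- data.frame(chrom = cfg$chrom, pos = as.numeric(pos_all),
                      id = sprintf("site%d", seq_len(S)), ref = ref, alt = alt,
                      ancestral_state = anc, multiallelic = FALSE,
                      stringsAsFactors = FALSE)

  groups <- c(rep("modern_noncarrier", nm), rep("archaic", 2L * na))
  if (n_carrier > 0)
    groups[match(truth$carrier_ids, rownames(alleles))] <- "modern_carrier"
  samples <- sub("_[12]$", "", rownames(alleles))
  panel <- haplotype_panel(alleles, sites, groups, samples)

  map <- genetic_map(c(1, L), c(0, (L - 1) * rate_cM_per_bp), chrom = cfg$chrom)
  mask <- region_mask(cfg$chrom, 0, L)
  list(panel = panel, map = map, mask = mask, truth = truth, config = cfg)
}

#' Simulate archaic fragment genetic lengths
#'
#' I.i.d. Exponential lengths, the single-sided recombination-clock model
#' for called archaic fragments.
#'
#' @param n number of fragments (>= 1)
#' @param mean_cM mean fragment genetic length (cM, > 0)
#' @param seed RNG seed
#' @return numeric vector of lengths (cM)
#' @export
simulate_fragments <- function(n, mean_cM, seed = 1L) {
  if (length(n) != 1L || n < 1) stop("n must be >= 1", call. = FALSE)
  if (mean_cM <= 0) stop("mean_cM must be positive", call. = FALSE)
  with_seed(seed, rexp(n, rate = 1 / mean_cM))
}

#' Simulate a noisy dose-response table
#'
#' Velocities are the deterministic kinetic model plus i.i.d. Gaussian
#' noise, per replicate.
#'
#' @param model `"michaelis_menten"` or `"substrate_inhibition"`
#' @param params list with `Vmax`, `Km` and (substrate inhibition) `Ki`
#' @param S_grid substrate concentrations (>= 0)
#' @param noise_sd Gaussian noise standard deviation (velocity units)
#' @param replicates replicates per concentration
#' @param seed RNG seed
#' @param condition condition label carried into the output
#' @return data.frame(condition, S, replicate, v)
#' @export
simulate_kinetic_dataset <- function(model, params, S_grid, noise_sd = 0,
                                     replicates = 1L, seed = 1L,
                                     condition = "cond1") {
  if (any(S_grid < 0)) stop("substrate concentrations must be >= 0", call. = FALSE)
  stopifnot(noise_sd >= 0, replicates >= 1)
  v0 <- velocity(model, S_grid, params)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      data.frame(condition = condition, S = S_grid, replicate = r,
                 v = v0 + rnorm(length(S_grid), 0, noise_sd))
    }))
    rownames(out) <- NULL
    out
  })
}
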