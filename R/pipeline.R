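#' Run the full synthetic end-to-end analysis
#'
#' simulate -> filter -> focal selection -> LD block -> genetic length ->
#' ILS test -> fragment percentile -> archaic affinity (distances, nearest
#' archaic, sharing track, bootstrap NJ tree) -> sliding Tajima's D, with
#' every stochastic stage seeded from the config and all seeds echoed in
#' the report.  Identical config gives byte-identical artifacts.
#'
#' The focal (proxy) variant is chosen as the site at which every archaic
#' genome carries the derived allele and the modern derived count is
#' maximal (ties broken towards the region centre); if no such site
#' segregates among moderns, the block/ILS/affinity stages are skipped
#' with reason `"no divergent block found"`.
#'
#' @param config a [sim_config()], or a list of overrides passed to it
#' @param out_dir optional directory; when given, writes block summary
#'   (TSV), ILS result (JSON), Newick tree, sharing track (TSV), Tajima
#'   track (TSV) and a machine-readable `report.json`
#' @param r2_threshold LD block r^2 cutoff
#' @param branch_human_gens,branch_archaic_gens ILS branch lengths
#'   (generations)
#' @param bootstrap NJ bootstrap replicates
#' @param n_fragments simulated genome-wide archaic fragments for the
#'   percentile stage
#' @param tajima_window,tajima_step sliding-scan geometry (bp)
#' @return a report list (also serialised to `report.json` under `out_dir`)
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         r2_threshold = 0.8,
                         branch_human_gens = 21500,
                         branch_archaic_gens = 19500,
                         bootstrap = 100L, n_fragments = 1000L,
                         tajima_window = 10000, tajima_step = 100) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  report <- list(seeds = list(simulate = config$seed,
                              bootstrap = config$seed + 1L,
                              fragments = config$seed + 2L))

  sim <- stage("simulate", simulate_panel(config))
  filtered <- stage("filter", filter_sites(sim$panel, sim$mask,
                                           drop_archaic_hets = TRUE))
  report$n_sites_raw <- n_sites(sim$panel)
  report$n_sites_filtered <- n_sites(filtered)
  report$truth <- sim$truth

  focal <- stage("focal", select_focal(filtered))
  tajima <- stage("tajima", sliding_tajima(
    subset_panel(filtered, haplotypes = grepl("^modern", filtered$groups)),
    window = tajima_window, step = tajima_step))

  if (is.na(focal)) {
    report$skipped <- "no divergent block found"
    report$block <- report$ils <- report$affinity <- NULL
  } else {
    block <- stage("block", call_block(filtered, focal,
                                       threshold = r2_threshold))
    gl <- stage("genetic_length", block_genetic_length(block, sim$map))
    ils <- stage("ils", ils_probability(gl, branch_human_gens,
                                        branch_archaic_gens))
    frags <- stage("fragments", simulate_fragments(
      n_fragments, mean_cM = 2 * 100 / config$admixture_generations,
      seed = report$seeds$fragments))
    report$block <- list(
      focal = block$focal$pos,
      upstream = block$upstream_boundary$pos,
      downstream = block$downstream_boundary$pos,
      span_bp = block$span_bp, span = format_kb(block$span_bp),
      genetic_length_cM = gl, threshold = r2_threshold)
    report$ils <- list(m_cM = ils$m_cM, G = ils$G,
                       expected_length_cM = ils$expected_length_cM,
                       probability = ils$probability)
    report$fragment_percentile <- fragment_percentile(gl, frags)

    aff <- stage("affinity", affinity_stage(filtered, block, bootstrap,
                                            report$seeds$bootstrap))
    report$affinity <- aff$summary
    block_obj <- block
    tree_obj <- aff$tree
    sharing <- aff$sharing
  }

  report$tajima <- list(window = tajima_window, step = tajima_step,
                        n_positions = nrow(tajima),
                        mean_D = mean(tajima$D, na.rm = TRUE))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(as.data.table(tajima), file.path(out_dir, "tajima_track.tsv"),
           sep = "\t")
    if (is.na(focal)) {
      for (f in c("block.tsv", "ils.json", "tree.nwk", "sharing_track.tsv"))
        unlink(file.path(out_dir, f))
    } else {
      fwrite(as.data.table(block_obj$profile), file.path(out_dir, "block.tsv"),
             sep = "\t")
      jsonlite::write_json(report$ils, file.path(out_dir, "ils.json"),
                           auto_unbox = TRUE, digits = NA)
      ape::write.tree(tree_obj$tree, file.path(out_dir, "tree.nwk"))
      fwrite(as.data.table(sharing), file.path(out_dir, "sharing_track.tsv"),
             sep = "\t")
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  invisible(report)
}

# focal proxy variant: derived in every archaic, segregating in moderns,
# max modern derived count, ties broken towards the region centre
select_focal <- function(panel) {
  arch <- panel$groups == "archaic"
  mod <- grepl("^modern", panel$groups)
  if (!any(arch) || !any(mod)) return(NA_real_)
  all_arch <- colSums(panel$alleles[arch, , drop = FALSE]) == sum(arch)
  mcount <- colSums(panel$alleles[mod, , drop = FALSE])
  cand <- which(all_arch & mcount > 0 & mcount < sum(mod))
  if (!length(cand)) return(NA_real_)
  best <- cand[mcount[cand] == max(mcount[cand])]
  centre <- (min(panel$sites$pos) + max(panel$sites$pos)) / 2
  panel$sites$pos[best[which.min(abs(panel$sites$pos[best] - centre))]]
}

affinity_stage <- function(filtered, block, bootstrap, seed) {
  blockp <- subset_panel(filtered, region = sprintf(
    "%s:%.0f-%.0f", block$focal$chrom,
    block$upstream_boundary$pos, block$downstream_boundary$pos))
  blockp <- collapse_archaics(blockp)
  carriers <- rownames(blockp$alleles)[blockp$groups == "modern_carrier"]
  archaics <- rownames(blockp$alleles)[blockp$groups == "archaic"]
  nearest <- lapply(carriers, function(h)
    nearest_archaic(blockp$alleles[h, ],
                    blockp$alleles[archaics, , drop = FALSE]))
  names(nearest) <- carriers
  sharing <- if (length(carriers))
    allele_sharing_track(blockp, "modern_carrier", "modern_noncarrier",
                         archaics[1L])
  else NULL
  treep <- add_ancestral_haplotype(blockp)
  # ancestral row first so deduplication keeps it as its own representative
  treep <- subset_panel(treep, haplotypes = order(treep$groups != "ancestral"))
  dd <- dedup_haplotypes(treep)
  tree <- nj_tree(dd$panel, outgroup = "ancestral", bootstrap = bootstrap,
                  seed = seed)
  reps <- names(dd$members)
  clade_taxa <- reps[vapply(dd$members, function(m)
    any(m %in% c(carriers, archaics)), logical(1L))]
  supp <- if (length(clade_taxa) >= 2 && length(clade_taxa) < length(reps))
    clade_support(dd$panel, clade_taxa, bootstrap = bootstrap,
                  seed = seed, outgroup = "ancestral")
  else list(support = NA_real_, observed = NA)
  list(tree = tree, sharing = sharing,
       summary = list(
         n_unique_haplotypes = n_haplotypes(dd$panel),
         nearest = lapply(nearest, function(x) x[c("label", "count")]),
         carrier_archaic_clade_support = supp$support,
         carrier_archaic_clade_observed = supp$observed))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `filter`, `block`, `ils`,
#' `fragrank`, `tree`, `share`, `tajima`, `kinfit` and `run`.  Options are
#' `--key value` pairs; `--help` (or no arguments) prints usage with every
#' default.  Results go to files or, for scalar results, JSON on stdout.
#' Installed as the `archintro` executable (see `exec/`).
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`
#' @return exit status, invisibly
#' @export
archintro_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: archintro <command> [--key value ...]",
    "",
    "commands:",
    "  simulate --out DIR [--seed 1] [--carrier-fraction 0.05] [--g 2000]",
    "  filter   --vcf F --out F2 [--mask BED] [--keep-archaic-hets]",
    "           [--archaic S1,S2]",
    "  block    --vcf F --focal chrom:pos [--r2 0.8] [--window 1000000]",
    "           [--map TSV] [--archaic S1,S2]",
    "  ils      --cm X [--branch-a 21500] [--branch-b 19500] [--sides 2]",
    "  fragrank --query-cm X --fragments TSV",
    "  tree     --vcf F --out NWK [--outgroup ancestral] [--boot 100]",
    "           [--seed 1] [--archaic S1,S2]",
    "  share    --vcf F --archaic S1,S2 --carriers S3,S4 --out TSV",
    "  tajima   --vcf F --out TSV [--region chrom:a-b] [--window 10000]",
    "           [--step 100]",
    "  kinfit   --data TSV [--model substrate_inhibition] [--km shared|free",
    "           |fixed] [--km-value X]",
    "  run      --out DIR [--seed 1] [--boot 100] [--step 100]",
    sep = "\n")
  if (!length(args) || args[1L] %in% c("--help", "-h", "help")) {
    cat(usage, "\n"); return(invisible(0L))
  }
  cmd <- args[1L]
  opt <- parse_cli_opts(args[-1L])
  emit <- function(x) cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           null = "null", force = TRUE), "\n")
  num <- function(key, default = NULL) {
    if (!is.null(opt[[key]])) as.numeric(opt[[key]]) else default
  }
  load_vcf <- function() {
    arch <- if (!is.null(opt$archaic)) strsplit(opt$archaic, ",")[[1L]]
            else character()
    carr <- if (!is.null(opt$carriers)) strsplit(opt$carriers, ",")[[1L]]
            else character()
    read_phased_vcf(opt$vcf, region = opt$region, archaic_samples = arch,
                    carrier_samples = carr)
  }
  switch(cmd,
    simulate = {
      cfg <- sim_config(seed = as.integer(num("seed", 1)),
                        carrier_fraction = num("carrier-fraction", 0.05),
                        admixture_generations = num("g", 2000))
      sim <- simulate_panel(cfg)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      write_panel_vcf(sim$panel, file.path(opt$out, "panel.vcf"),
                      header_extra = sprintf("##archintro_seed=%d", cfg$seed))
      write_genetic_map(sim$map, file.path(opt$out, "map.tsv"))
      write_mask(sim$mask, file.path(opt$out, "mask.bed"))
      jsonlite::write_json(sim$truth, file.path(opt$out, "truth.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      message("wrote panel.vcf, map.tsv, mask.bed, truth.json to ", opt$out)
    },
    filter = {
      panel <- load_vcf()
      mask <- if (!is.null(opt$mask)) read_mask(opt$mask) else NULL
      panel <- filter_sites(panel, mask,
                            drop_archaic_hets = is.null(opt$`keep-archaic-hets`))
      write_panel_vcf(panel, opt$out)
    },
    block = {
      panel <- filter_sites(load_vcf())
      reg <- parse_region(paste0(opt$focal, "-",
                                 sub(".*:", "", opt$focal)))
      blk <- call_block(panel, reg$start, threshold = num("r2", 0.8),
                        max_window_bp = num("window", 1e6))
      out <- list(focal = blk$focal$pos, upstream = blk$upstream_boundary$pos,
                  downstream = blk$downstream_boundary$pos,
                  span_bp = blk$span_bp, span = format_kb(blk$span_bp))
      if (!is.null(opt$map))
        out$genetic_length_cM <-
          block_genetic_length(blk, read_genetic_map(opt$map))
      emit(out)
    },
    ils = {
      r <- ils_probability(num("cm"), num("branch-a", 21500),
                           num("branch-b", 19500), sides = num("sides", 2))
      emit(unclass(r))
    },
    fragrank = emit(list(
      query_cM = num("query-cm"),
      percentile = fragment_percentile(num("query-cm"),
                                       read_fragments(opt$fragments)))),
    tree = {
      panel <- add_ancestral_haplotype(collapse_archaics(
        filter_sites(load_vcf())))
      tr <- nj_tree(dedup_haplotypes(panel)$panel,
                    outgroup = opt$outgroup %||% "ancestral",
                    bootstrap = as.integer(num("boot", 100)),
                    seed = as.integer(num("seed", 1)))
      ape::write.tree(tr$tree, opt$out)
      message("wrote ", opt$out)
    },
    share = {
      panel <- collapse_archaics(filter_sites(load_vcf()))
      arch <- rownames(panel$alleles)[panel$groups == "archaic"][1L]
      tr <- allele_sharing_track(panel, "modern_carrier",
                                 "modern_noncarrier", arch)
      fwrite(as.data.table(tr), opt$out, sep = "\t")
    },
    tajima = {
      panel <- filter_sites(load_vcf())
      panel <- subset_panel(panel,
                            haplotypes = grepl("^modern", panel$groups))
      tr <- sliding_tajima(panel, region = opt$region,
                           window = num("window", 10000),
                           step = num("step", 100))
      fwrite(as.data.table(tr), opt$out, sep = "\t")
    },
    kinfit = {
      dat <- as.data.frame(fread(opt$data))
      fit <- global_fit(dat, model = opt$model %||% "substrate_inhibition",
                        km_mode = opt$km %||% "shared",
                        km_value = num("km-value"))
      emit(list(model = fit$model, km_mode = fit$km_mode, Km = fit$Km,
                Ki = fit$Ki, rss = fit$rss, fits = fit$fits))
    },
    run = {
      rep <- run_pipeline(sim_config(seed = as.integer(num("seed", 1))),
                          out_dir = opt$out,
                          bootstrap = as.integer(num("boot", 100)),
                          tajima_step = num("step", 100))
      message("report written to ", file.path(opt$out, "report.json"))
    },
    { cat(usage, "\n"); stop("unknown command '", cmd, "'", call. = FALSE) })
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument '", args[i], "'", call. = FALSE)
    key <- substring(args[i], 3L)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opt[[key]] <- args[i + 1L]; i <- i + 2L
    } else {
      opt[[key]] <- TRUE; i <- i + 1L
    }
  }
  opt
}
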