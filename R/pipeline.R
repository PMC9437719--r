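#' Pipeline configuration
#'
#' Collects stage parameters for [run_pipeline()]. Defaults are the
#' values used throughout the package: 500 kb binning windows,
#' independence LOD 9 for grouping, at most 9 missing calls per mapped
#' marker, LOD 2.5 interval-mapping significance, Kruskal-Wallis
#' significance 0.005 and 10 cM cross-environment QTL matching.
#'
#' @param sim a [sim_config()] for the simulate stage.
#' @param out_dir artifact directory.
#' @param window_bp,ind_lod_min,max_missing,lod_threshold,kw_alpha,tol_cM
#'   stage parameters.
#' @param qtl_spec planted QTLs for simulated traits (see
#'   [simulate_traits()]).
#' @param h2_polygenic polygenic background for simulated traits.
#' @param n_scaffolds,misassign_rate,unplaced_rate fragmentation stage.
#' @param seed master seed; per-stage seeds derive from it.
#' @param verbose print stage progress.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_chrom = 3,
                                             snps_per_chrom = 300,
                                             chrom_len_bp = 15e6),
                            out_dir = tempfile("sibmap_run_"),
                            window_bp = 500000, ind_lod_min = 9,
                            max_missing = 9, lod_threshold = 2.5,
                            kw_alpha = 0.005, tol_cM = 10,
                            qtl_spec = list(), h2_polygenic = 0.3,
                            n_scaffolds = 30, misassign_rate = 0.2,
                            unplaced_rate = 0.25,
                            seed = 1L, verbose = TRUE) {
  stopifnot(inherits(sim, "sim_config"))
  if (window_bp <= 0 || ind_lod_min < 0 || max_missing < 0 ||
      lod_threshold < 0 || kw_alpha <= 0 || kw_alpha >= 1 || tol_cM <= 0)
    stop_input("invalid stage parameter")
  structure(list(sim = sim, out_dir = out_dir, window_bp = window_bp,
                 ind_lod_min = ind_lod_min, max_missing = max_missing,
                 lod_threshold = lod_threshold, kw_alpha = kw_alpha,
                 tol_cM = tol_cM, qtl_spec = qtl_spec,
                 h2_polygenic = h2_polygenic, n_scaffolds = n_scaffolds,
                 misassign_rate = misassign_rate,
                 unplaced_rate = unplaced_rate,
                 seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

PIPELINE_STAGES <- c("simulate", "classify", "bin", "map", "qtl", "synteny")

#' Run the full analysis chain on a simulated population
#'
#' Executes simulate -> classify -> bin -> map -> qtl -> synteny (or any
#' contiguous subset) with one derived RNG stream per stage, writing the
#' declared artifacts (VCF, CP genotype TSVs, bin BED/TSV, map TSVs, scan
#' and QTL report TSVs, collinearity TSV, AGP) plus a JSON run manifest
#' under `config$out_dir`. Reruns with the same configuration and seed
#' produce byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param from,to first and last stage to run.
#' @param state a previous invocation's return value, required when
#'   `from` is not `"simulate"`.
#' @return invisibly, a list with the stage objects (`pop`, `sites`,
#'   `bins`, `maps`, `consensus`, `scans`, `anchoring`, ...) and
#'   `artifacts` (paths written).
#' @export
run_pipeline <- function(config, from = "simulate", to = "synteny",
                         state = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  from_i <- match(from, PIPELINE_STAGES); to_i <- match(to, PIPELINE_STAGES)
  if (is.na(from_i) || is.na(to_i) || from_i > to_i)
    stop_input("stages must be a contiguous subset of: ",
               paste(PIPELINE_STAGES, collapse = " -> "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message("[sibmap] ", ...)
  art <- list()
  put <- function(name) { p <- file.path(config$out_dir, name); art[[name]] <<- p; p }
  run_stage <- function(stage, expr) {
    set.seed(stage_seed(config$seed, stage))
    say("stage ", stage)
    tryCatch(expr, error = function(e)
      stop_input("stage '", stage, "' failed: ", conditionMessage(e)))
  }
  stages <- PIPELINE_STAGES[from_i:to_i]

  if ("simulate" %in% stages) {
    state$pop <- run_stage("simulate", {
      pop <- simulate_population(config$sim,
                                 seed = stage_seed(config$seed, "simulate"))
      write_vcf(pop, put("population.vcf"))
      write_sim_truth(pop$truth, file.path(config$out_dir, "truth"))
      pop
    })
  }
  if ("classify" %in% stages) {
    if (is.null(state$pop)) stop_input("stage 'classify' needs a population (run simulate first)")
    state$sites <- run_stage("classify", {
      snp <- mask_low_confidence(as_snp_data(state$pop))
      cp <- segregation_chi2(classify_segregation(snp))
      flt <- filter_sites(cp)
      write_cp_geno(flt$sites, put("snp_genotypes.tsv"), put("snp_sites.tsv"))
      write.table(flt$log, put("snp_rejections.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      flt$sites
    })
  }
  if ("bin" %in% stages) {
    if (is.null(state$sites)) stop_input("stage 'bin' needs classified sites")
    state$bins <- run_stage("bin", {
      bins <- bin_markers(state$sites, window_bp = config$window_bp)
      write_bins_bed(bins, put("bins.bed"))
      write_cp_geno(bins, put("bin_genotypes.tsv"), put("bin_markers.tsv"))
      bins
    })
  }
  if ("map" %in% stages) {
    if (is.null(state$bins)) stop_input("stage 'map' needs bin markers")
    got <- run_stage("map", {
      maps <- build_parental_maps(state$bins,
                                  ind_lod_min = config$ind_lod_min,
                                  max_missing = config$max_missing)
      cons <- suppressWarnings(
        merge_consensus(maps$maternal, maps$paternal, bins = state$bins,
                        ind_lod_min = config$ind_lod_min))
      write_map_tsv(maps$maternal, put("map_maternal.tsv"))
      write_map_tsv(maps$paternal, put("map_paternal.tsv"))
      write_map_tsv(cons, put("map_consensus.tsv"))
      write.table(map_summary(cons), put("map_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(maps = maps, consensus = cons)
    })
    state$maps <- got$maps; state$consensus <- got$consensus
  }
  if ("qtl" %in% stages) {
    if (is.null(state$consensus)) stop_input("stage 'qtl' needs a consensus map")
    got <- run_stage("qtl", {
      trait <- simulate_traits(state$pop$truth, qtl_spec = config$qtl_spec,
                               h2_polygenic = config$h2_polygenic,
                               seed = stage_seed(config$seed, "qtl"))
      probs <- transmission_probs(state$consensus, state$bins,
                                  eps = config$sim$error_rate)
      scan <- interval_mapping(trait, probs,
                               lod_threshold = config$lod_threshold)
      kw <- kw_scan(trait, state$bins, alpha = config$kw_alpha,
                    map = state$consensus)
      h2 <- tryCatch(heritability(state$bins, trait), error = function(e) {
        say("heritability skipped: ", conditionMessage(e))
        NULL
      })
      write.table(scan$curve, put("qtl_lod_curve.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(scan$peaks, put("qtl_peaks.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(kw, put("kw_scan.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      list(trait = trait, scan = scan, kw = kw, h2 = h2)
    })
    state[names(got)] <- got
  }
  if ("synteny" %in% stages) {
    if (is.null(state$consensus)) stop_input("stage 'synteny' needs a map")
    got <- run_stage("synteny", {
      frag <- fragment_genome(state$pop$truth, config$n_scaffolds,
                              misassign_rate = config$misassign_rate,
                              unplaced_rate = config$unplaced_rate,
                              seed = stage_seed(config$seed, "synteny"))
      coll <- classify_vs_reference(state$consensus, frag$reference,
                                    frag$layout)
      anch <- anchor_scaffolds(state$consensus, frag$layout)
      write.table(as.data.frame(coll), put("collinearity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_agp(anch$agp, put("reanchored.agp"))
      write_agp(frag$agp, put("truth.agp"), comment = "true layout")
      list(fragmentation = frag, collinearity = coll, anchoring = anch)
    })
    state[names(got)] <- got
  }
  manifest <- list(
    package = "sibmap",
    version = as.character(utils::packageVersion("sibmap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = setNames(lapply(stages, stage_seed, seed = config$seed),
                           stages),
    parameters = config[c("window_bp", "ind_lod_min", "max_missing",
                          "lod_threshold", "kw_alpha", "tol_cM",
                          "n_scaffolds", "misassign_rate", "unplaced_rate")],
    sim = unclass(config$sim),
    artifacts = lapply(art, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state$artifacts <- art
  invisible(state)
}
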