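#' Run the full two-population analysis pipeline
#'
#' Orchestrates qc -> polarize -> diversity -> SFS -> load -> ROH ->
#' Fst/enrichment from a single declarative config and writes every
#' stage's table plus a manifest into the output directory. Rerunning
#' with the same config and master seed reproduces byte-identical
#' outputs. Per-stage seeds are fanned out deterministically from the
#' master seed (`seed + stage index`), so a stage rerun in isolation
#' matches its output in the full run.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `input` (`vcf`, `panel`, `annotation`, optional `catalog`) or
#'   `simulate` (overrides for [scenario_params()]); `target` and
#'   `reference` population labels; `seed`; `out` (output directory);
#'   optional stage blocks `qc` (logical `enabled` plus
#'   [qc_thresholds()] overrides), `diversity`/`load` (`n_blocks`,
#'   `n_reps`), `sfs` (`n_sub`, `test_n_sub`, `n_reps`), `roh`
#'   ([roh_params()] overrides, `prune`), `enrichment`
#'   (`top_fraction`, `n_reps`).
#' @return List of stage results (invisibly also written as TSVs under
#'   `config$out`), plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$target), !is.null(config$reference))
  if (is.null(config$seed)) config$seed <- 1L
  out_dir <- config$out %||% tempfile("isodist_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed_of <- function(stage)
    config$seed + match(stage, c("simulate", "diversity", "sfs", "load",
                                 "roh", "enrichment"))

  manifest <- list(config = config[setdiff(names(config), "out")],
                   stages = list())
  note <- function(stage, files, params) {
    # manifest paths are relative to the run directory so reruns into
    # different directories stay byte-identical
    rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out_dir), "/?"),
               "", unname(files))
    manifest$stages[[stage]] <<- list(files = rel, params = params)
  }

  # ---- input ----
  if (!is.null(config$simulate)) {
    sp <- do.call(scenario_params,
                  c(config$simulate[names(config$simulate) != "preset"],
                    list(seed = seed_of("simulate"))))
    sim <- simulate_scenario(sp, file.path(out_dir, "simulated"))
    input <- sim$paths
    note("simulate", unlist(input), list(seed = seed_of("simulate")))
  } else {
    input <- config$input
    for (k in c("vcf", "panel", "annotation"))
      if (is.null(input[[k]]) || !file.exists(input[[k]]))
        stop("missing input: ", k)
  }
  panel <- read_panel(input$panel)
  rv <- read_vcf(input$vcf, panel)
  sites <- annotate_sites(rv$sites, read_annotation(input$annotation))
  gm <- rv$gm

  # ---- qc ----
  qc_cfg <- config$qc %||% list(enabled = TRUE)
  if (isTRUE(qc_cfg$enabled %||% TRUE)) {
    thr <- do.call(qc_thresholds,
                   qc_cfg[intersect(names(qc_cfg), names(formals(qc_thresholds)))])
    fs <- qc_filter_sites(gm, sites, panel, thr)
    gm <- fs$gm; sites <- fs$sites
    write_stage_tsv(as.data.frame(t(unlist(fs$report$removed))),
                    out_dir, "qc_report.tsv")
    note("qc", "qc_report.tsv", fs$report)
  }
  pol <- polarize(gm, sites)
  gm <- pol$gm; sites <- pol$sites
  pops <- c(config$target, config$reference)

  # ---- diversity ----
  dv <- config$diversity %||% list()
  syn <- mask_synonymous(sites)
  div <- diversity_bootstrap(gm, panel, pops, site_mask = syn,
                             n_blocks = dv$n_blocks %||% 1000,
                             n_reps = dv$n_reps %||% 1000,
                             seed = seed_of("diversity"))
  seg <- segregating_site_summaries(gm, panel)
  write_stage_tsv(div, out_dir, "diversity.tsv")
  write_stage_tsv(seg, out_dir, "segregating_sites.tsv")
  note("diversity", c("diversity.tsv", "segregating_sites.tsv"),
       list(seed = seed_of("diversity"), mask = "synonymous"))

  # ---- sfs ----
  sf <- config$sfs %||% list()
  scheme <- category_scheme("gerp")
  sfs_rows <- list()
  for (pop in pops) {
    per_cat <- sfs_by_category(gm, panel, pop, sites, scheme,
                               n_sub = sf$n_sub %||% 8, seed = seed_of("sfs"))
    for (s in per_cat)
      sfs_rows[[length(sfs_rows) + 1L]] <- data.frame(
        population = pop, category = s$category,
        bin = as.integer(names(s$counts)), count = as.integer(s$counts),
        density = as.numeric(s$densities), stringsAsFactors = FALSE)
  }
  sfs_tab <- do.call(rbind, sfs_rows)
  lvc <- do.call(rbind, lapply(pops, function(pop)
    low_vs_common_proportions(gm, panel, pop, sites,
                              n_sub = sf$n_sub %||% 8, seed = seed_of("sfs"))))
  ddt <- density_difference_test(gm, panel, config$reference, config$target,
                                 sites, scheme,
                                 n_sub = sf$test_n_sub %||% 18,
                                 n_reps = sf$n_reps %||% 1000,
                                 seed = seed_of("sfs"))
  write_stage_tsv(sfs_tab, out_dir, "sfs.tsv")
  write_stage_tsv(lvc, out_dir, "low_vs_common.tsv")
  write_stage_tsv(ddt$tests, out_dir, "sfs_density_tests.tsv")
  note("sfs", c("sfs.tsv", "low_vs_common.tsv", "sfs_density_tests.tsv"),
       list(seed = seed_of("sfs"), n_sub = sf$n_sub %||% 8))

  # ---- load ----
  ld <- config$load %||% list()
  ratios <- load_ratio_table(gm, panel, config$target, config$reference, sites,
                             scheme = scheme,
                             consequence_filter = isTRUE(ld$consequence_filter),
                             n_blocks = ld$n_blocks %||% 1000,
                             n_reps = ld$n_reps %||% 1000,
                             seed = seed_of("load"))
  gerp_load <- do.call(rbind, lapply(pops, function(pop)
    do.call(rbind, lapply(c("additive", "recessive"), function(model) {
      gl <- gerp_score_load(gm, panel, pop, sites, model = model)
      data.frame(population = pop, model = model,
                 category = names(gl$per_category),
                 load = as.numeric(gl$per_category),
                 total = gl$total, stringsAsFactors = FALSE)
    }))))
  write_stage_tsv(ratios, out_dir, "load_ratios.tsv")
  write_stage_tsv(gerp_load, out_dir, "gerp_load.tsv")
  note("load", c("load_ratios.tsv", "gerp_load.tsv"),
       list(seed = seed_of("load")))

  # ---- roh ----
  rc <- config$roh %||% list()
  rp <- do.call(roh_params,
                rc[intersect(names(rc), names(formals(roh_params)))])
  roh_gm <- gm; roh_sites <- sites
  if (isTRUE(rc$prune %||% TRUE)) {
    keep <- ld_prune(gm, sites, rp$prune_window_kb, rp$prune_step_snps,
                     rp$r2_prune)
    roh_gm <- gm_subset(gm, sites = keep)
    roh_sites <- sites[keep, , drop = FALSE]
  }
  rohs <- detect_rohs_all(roh_gm, roh_sites, rp)
  rs <- roh_summaries(rohs, panel, rp,
                      pairs = matrix(pops, ncol = 2))
  zr <- roh_zygosity_ratio(gm, sites, rohs, panel, rp, scheme)
  write_stage_tsv(rohs, out_dir, "rohs.tsv")
  write_stage_tsv(rs$per_individual, out_dir, "roh_summaries.tsv")
  if (!is.null(rs$tests)) write_stage_tsv(rs$tests, out_dir, "roh_tests.tsv")
  write_stage_tsv(zr$ratios, out_dir, "roh_zygosity_ratios.tsv")
  note("roh", c("rohs.tsv", "roh_summaries.tsv", "roh_tests.tsv",
                "roh_zygosity_ratios.tsv"), rp)

  # ---- fst / enrichment ----
  en <- config$enrichment %||% list()
  fst_rec <- per_site_fst(gm, panel, config$target, config$reference)
  subsets <- build_candidate_subsets(gm, sites, fst_rec$fst, panel,
                                     config$target, config$reference,
                                     top_fraction = en$top_fraction %||% 0.05)
  subset_tab <- do.call(rbind, lapply(names(subsets), function(nm)
    data.frame(subset = nm, n_sites = length(subsets[[nm]]$sites),
               genes = paste(subsets[[nm]]$genes, collapse = ","),
               stringsAsFactors = FALSE)))
  peaks <- fst_peaks(fst_rec$fst, sites)
  write_stage_tsv(cbind(sites[, c("chrom", "pos")], fst = fst_rec$fst),
                  out_dir, "fst.tsv")
  write_stage_tsv(subset_tab, out_dir, "candidate_subsets.tsv")
  write_stage_tsv(peaks, out_dir, "fst_peaks.tsv")
  enr <- boot_enr <- NULL
  catalog_path <- input$catalog %||% config$input$catalog
  if (!is.null(catalog_path)) {
    catalog <- read_catalog(catalog_path)
    universe <- unique(sites$gene[sites$gene != ""])
    query <- subsets$all_categories$genes
    if (length(query)) {
      enr <- ora(query, universe, catalog)
      boot_enr <- catalog_bootstrap_enrichment(query, catalog, universe,
                                               n_reps = en$n_reps %||% 1000,
                                               seed = seed_of("enrichment"))
      write_stage_tsv(enr, out_dir, "ora.tsv")
      write_stage_tsv(boot_enr, out_dir, "catalog_bootstrap.tsv")
    }
  }
  note("enrichment", c("fst.tsv", "candidate_subsets.tsv", "fst_peaks.tsv",
                       "ora.tsv", "catalog_bootstrap.tsv"),
       list(seed = seed_of("enrichment"),
            top_fraction = en$top_fraction %||% 0.05))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(gm = gm, sites = sites, panel = panel, diversity = div,
                 segregating = seg, sfs = sfs_tab, low_vs_common = lvc,
                 sfs_tests = ddt$tests, load_ratios = ratios,
                 gerp_load = gerp_load, rohs = rohs, roh_summaries = rs,
                 roh_zygosity = zr, fst = fst_rec, subsets = subsets,
                 peaks = peaks, ora = enr, catalog_bootstrap = boot_enr,
                 out_dir = out_dir, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_stage_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(name)
}
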