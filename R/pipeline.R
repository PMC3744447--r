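# configuration container and the umbrella end-to-end run

pipeline_defaults <- function() {
  list(
    window = 2000,          # scan window width, bp
    step = 500,             # scan stride, bp
    alpha = 1e-3,           # per-window significance threshold
    mapq_min = 10,          # mapping-quality filter
    profile_bin = 100,      # TSS metaprofile bin, bp
    profile_range = 2000,   # TSS metaprofile half-range, bp
    sine_window = 50000,    # SINE density window, bp
    sine_step = 5000,       # SINE density offset spacing, bp
    sine_range = 100000,    # SINE density half-range, bp
    fold_threshold = 1.24,  # induction fold cutoff
    p_threshold = 0.05,     # adjusted-p cutoff for gene grouping
    pwm_threshold_frac = 0.8,  # motif hit threshold, fraction of max score
    coloc_threshold_nm = 225,  # locus-to-factory colocalization rule
    k_rnap = 1,             # RNAPII positive-voxel SD multiplier
    k_fish = 2,             # FISH object SD multiplier
    min_volume = 2,         # minimum object size, voxels
    dz_nm = 200,            # axial voxel size, nm
    seed = 1
  )
}

#' Build a validated pipeline configuration
#'
#' Defaults carry the analysis constants of the study design (2-kb
#' windows, alpha 1e-3, 100-bp TSS bins, 50-kb/5-kb SINE windows,
#' 1.24-fold induction threshold, 225-nm colocalization rule, mean+1SD
#' RNAPII threshold, 200-nm z spacing). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @param path Optional JSON file of overrides (an empty object keeps all
#'   defaults).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., path = NULL) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (!is.null(path)) {
    file_over <- jsonlite::read_json(path, simplifyVector = TRUE)
    over <- utils::modifyList(as.list(file_over), over)
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, over)
  with(cfg, {
    stopifnot(window > 0, step > 0, step <= window,
              alpha > 0, alpha < 1,
              profile_bin > 0, profile_range %% profile_bin == 0,
              sine_window > 0, sine_step > 0, sine_range %% sine_step == 0,
              fold_threshold > 1, p_threshold > 0, p_threshold < 1,
              pwm_threshold_frac > 0, pwm_threshold_frac <= 1,
              coloc_threshold_nm > 0, k_rnap > 0, k_fish > 0,
              min_volume >= 1, dz_nm > 0)
  })
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the genomic pipeline end to end on synthetic data
#'
#' Generates a seeded synthetic study (annotation, expression table,
#' acetylated SINEs, and a pair of tag libraries with 3x spikes placed
#' over the SINEs planted near stimulus-induced genes), then runs the
#' full chain: window scan, region calling, changes track, gene grouping,
#' genomic-context classification, acetylated-SINE calling, SINE density
#' profile and B-box over-representation. All outputs and a
#' machine-readable manifest (with md5 digests) are written under
#' `out_dir`; reruns with the same configuration are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_genes Cohort sizes of the synthetic study.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         n_genes = c(CS = 20, CE = 30, NI = 30, NR = 10)) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  ann <- sim_annotation(n_genes = n_genes, fold_threshold = config$fold_threshold,
                        seed = seed)
  # spike acetylation gains over the SINEs planted near NI genes
  surplus <- ann$truth$surplus
  spikes <- NULL
  if (!is.null(surplus) && nrow(surplus) > 0) {
    ctr <- surplus$start + 75L
    spikes <- tibble(chrom = "chrS",
                     start = pmax(0L, as.integer(ctr - config$window / 2)),
                     end = as.integer(ctr + config$window / 2),
                     ratio = 3)
  }
  libs <- sim_tag_libraries(ann$chrom_sizes, spikes = spikes, seed = seed + 1)
  windows <- scan_windows(libs$lib_a, libs$lib_b, window = config$window,
                          step = config$step, alpha = config$alpha)
  regions <- merge_significant(windows, alpha = config$alpha)
  expr <- classify_genes(ann$expression, fold_threshold = config$fold_threshold,
                         p_threshold = config$p_threshold)
  genes <- dplyr::left_join(ann$genes[, setdiff(names(ann$genes), "group")],
                            expr[, c("gene_id", "group")], by = "gene_id")
  ctx <- classify_region_context(regions, genes)
  ac <- acetylated_sines(regions, ann$repeats)
  profile <- sine_density_profile(ac, genes, ann$chrom_sizes,
                                  window = config$sine_window,
                                  step = config$sine_step,
                                  range = config$sine_range)
  mot <- sim_sequences(60, 400, plant_frac = 0.5, seed = seed + 2)
  enr <- motif_overrepresentation(
    bbox_pwm(), mot$seqs[mot$truth$planted], mot$seqs[!mot$truth$planted],
    threshold = config$pwm_threshold_frac * pwm_max_score(bbox_pwm()))

  p <- function(f) file.path(out_dir, f)
  write_changes_track(regions, p("changes.wig"), alpha = config$alpha)
  write_regions_bed(regions, p("regions.bed"))
  readr::write_tsv(glance(regions), p("region_summary.tsv"))
  readr::write_tsv(dplyr::count(ctx, .data$direction, .data$context),
                   p("region_context.tsv"))
  readr::write_tsv(expr, p("gene_groups.tsv"))
  readr::write_tsv(ac, p("acetylated_sines.tsv"))
  readr::write_tsv(as_tibble(profile), p("sine_profile.tsv"))
  readr::write_tsv(profile_tests(profile), p("sine_profile_tests.tsv"))
  readr::write_tsv(enr, p("motif_overrepresentation.tsv"))
  summary_tbl <- glance(windows)
  readr::write_tsv(summary_tbl, p("scan_summary.tsv"))
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "sineac",
    version = as.character(utils::packageVersion("sineac")),
    seed = seed,
    config = unclass(config),
    outputs = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(windows = windows, regions = regions, context = ctx,
                 genes = genes, acetylated_sines = ac, profile = profile,
                 motif = enr, manifest = manifest))
}
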