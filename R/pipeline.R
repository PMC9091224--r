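#' Assemble a pipeline configuration
#'
#' @param outdir output directory.
#' @param spec a [cohort_spec()] describing the synthetic cohort to analyze
#'   (stage inputs are taken from the simulated bundle).
#' @param stages character vector of stages to run, a subset of
#'   `c("io", "tinda", "kataegis", "signatures", "cnv", "integration",
#'   "telomere", "expression")`.
#' @param seed global seed; per-stage seeds derive from it by stable
#'   hashing of the stage name.
#' @param params list of stage parameters: `min_snvs`, `max_imd`,
#'   `smoothing` ([smoothing_params()]), `tinda_k`, `tinda_threshold`,
#'   `cutoffs`, `telomere_threshold`, `min_recurrence`.
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(outdir, spec = cohort_spec(),
                            stages = c("io", "tinda", "kataegis",
                                       "signatures", "cnv", "integration",
                                       "telomere", "expression"),
                            seed = 1, params = list()) {
  defaults <- list(min_snvs = 6, max_imd = 1000,
                   smoothing = smoothing_params(), tinda_k = 9,
                   tinda_threshold = 0.75, cutoffs = 0,
                   telomere_threshold = 6, min_recurrence = 5)
  params <- utils::modifyList(defaults, params)
  structure(list(outdir = outdir, spec = spec, stages = stages, seed = seed,
                 params = params),
            class = "PipelineConfig")
}

# stable per-stage seed: global seed + decimal hash of the stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((seed * 10007 + h) %% 2147483647)
}

#' Run the analysis pipeline end to end on a synthetic cohort
#'
#' Simulates the cohort described by the config spec, runs the enabled
#' stages in dependency order and writes every stage's TSV outputs plus a
#' manifest (file, md5 checksum, stage). Reruns with the same config are
#' checksum-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest data frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, f)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = f, md5 = unname(tools::md5sum(f)),
      stringsAsFactors = FALSE)
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  p <- config$params
  bundle <- simulate_cohort(config$spec)
  labels <- stats::setNames(bundle$meta$subgroup, bundle$meta$sample)

  run_stage("io", function() {
    files <- write_cohort(bundle, file.path(config$outdir, "cohort"))
    for (f in files) note("io", f)
  })

  variants <- bundle$variants
  run_stage("tinda", function() {
    res <- lapply(names(bundle$tinda_points), function(sm)
      run_tinda(bundle$tinda_points[[sm]], k = p$tinda_k,
                seed = stage_seed(config$seed, paste0("tinda.", sm)),
                threshold = p$tinda_threshold)$points)
    names(res) <- names(bundle$tinda_points)
    summ <- rescue_summary(res)
    f <- file.path(config$outdir, "tinda_rescued.tsv")
    write.table(data.frame(sample = names(summ$per_sample),
                           rescued = summ$per_sample), f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("tinda", f)
  })

  run_stage("kataegis", function() {
    regions <- detect_hotspots(variants, min_snvs = p$min_snvs,
                               max_mean_imd = p$max_imd)
    f <- file.path(config$outdir, "kataegis_regions.tsv")
    write.table(regions, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("kataegis", f)
    genes_hit <- annotate_hotspot_genes(regions, bundle$genes)
    f <- file.path(config$outdir, "kataegis_genes.tsv")
    write.table(genes_hit, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("kataegis", f)
  })

  run_stage("signatures", function() {
    cat96 <- build_sbs96_catalog(variants, bundle$genome)
    lcd <- decompose_lcd(cat96, config$spec$signatures, cutoffs = p$cutoffs)
    f <- file.path(config$outdir, "exposures.tsv")
    write_matrix_tsv(lcd$exposures, f, id_col = "signature")
    note("signatures", f)
    f <- file.path(config$outdir, "exposures_normalized.tsv")
    write_matrix_tsv(lcd$normalized, f, id_col = "signature")
    note("signatures", f)
  })

  smoothed <- NULL
  run_stage("cnv", function() {
    smoothed <<- smooth_cohort_segments(bundle$segments, p$smoothing)
    f <- file.path(config$outdir, "segments_smoothed.tsv")
    write_segments(smoothed, f)
    note("cnv", f)
    ev <- do.call(rbind, lapply(bundle$meta$sample, function(sm) {
      e <- call_arm_events(smoothed[smoothed$sample == sm, ],
                           bundle$genome,
                           bundle$meta$ploidy[bundle$meta$sample == sm])
      if (nrow(e)) cbind(sample = sm, e) else NULL
    }))
    f <- file.path(config$outdir, "arm_events.tsv")
    write.table(ev, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("cnv", f)
    fag <- vapply(bundle$meta$sample, function(sm)
      fraction_aberrant_genome(smoothed[smoothed$sample == sm, ],
                               bundle$meta$ploidy[bundle$meta$sample == sm]),
      0)
    f <- file.path(config$outdir, "fraction_aberrant.tsv")
    write.table(data.frame(sample = names(fag), fag = fag), f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("cnv", f)
  })

  run_stage("integration", function() {
    filtered <- filter_recurrent_artifact_indels(variants)
    sv_annot <- if (!is.null(bundle$svs))
      annotate_sv_to_genes(bundle$svs, bundle$genes) else NULL
    seg_use <- if (!is.null(smoothed)) smoothed else
      smooth_cohort_segments(bundle$segments, p$smoothing)
    focal <- lapply(stats::setNames(bundle$meta$sample, bundle$meta$sample),
                    function(sm)
      classify_focal_cna(seg_use[seg_use$sample == sm, ], bundle$genome,
                         bundle$genes,
                         bundle$meta$ploidy[bundle$meta$sample == sm]))
    am <- build_alteration_matrix(filtered, sv_annot, focal,
                                  samples = bundle$meta$sample)
    f <- file.path(config$outdir, "alterations.tsv")
    write.table(am$long, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("integration", f)
    groups <- unique(bundle$meta$subgroup)
    if (length(groups) >= 2) {
      rc <- recurrence_compare(am, labels, groups[1], groups[2])
      f <- file.path(config$outdir, "recurrence_compare.tsv")
      write.table(rc, f, sep = "\t", quote = FALSE, row.names = FALSE)
      note("integration", f)
    }
    me <- tryCatch(mutual_exclusivity(am, min_recurrence = p$min_recurrence),
                   error = function(e) NULL)
    if (!is.null(me)) {
      f <- file.path(config$outdir, "mutual_exclusivity.tsv")
      write.table(me, f, sep = "\t", quote = FALSE, row.names = FALSE)
      note("integration", f)
    }
  })

  run_stage("telomere", function() {
    res <- lapply(bundle$meta$sample, function(sm) {
      est <- list()
      for (kind in c("tumor", "control")) {
        sc <- scan_telomeric_reads(
          bundle$telomere_reads[[paste0(sm, ".", kind)]],
          threshold_per_100bp = p$telomere_threshold)
        est[[kind]] <- telomere_content(sc$n_telomeric, sc$n_gc_matched)
      }
      tcc <- bundle$meta$tcc[bundle$meta$sample == sm]
      data.frame(sample = sm, content_tumor = est$tumor,
                 content_control = est$control, tcc = tcc,
                 content_corrected = as.numeric(
                   tcc_correct(est$tumor, est$control, tcc)),
                 stringsAsFactors = FALSE)
    })
    f <- file.path(config$outdir, "telomere_content.tsv")
    write.table(do.call(rbind, res), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("telomere", f)
  })

  run_stage("expression", function() {
    tq <- compute_tpm(bundle$counts, bundle$gene_meta)
    f <- file.path(config$outdir, "tpm.tsv")
    write_matrix_tsv(tq$tpm, f)
    note("expression", f)
    ig <- ig_constant_profile(tq$tpm,
                              c("IGHM", paste0("IGHG", 1:4), "IGHA1",
                                "IGHA2", "IGHD", "IGHE", "IGKC", "IGLC2"))
    f <- file.path(config$outdir, "ig_dominant.tsv")
    write.table(data.frame(sample = names(ig$dominant),
                           dominant = ig$dominant), f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("expression", f)
    tumor_sm <- bundle$meta$sample[1]
    mixed <- mix_profiles(bundle$counts[, tumor_sm],
                          bundle$background_profile,
                          seed = stage_seed(config$seed, "dilution"))
    f <- file.path(config$outdir, "dilution_counts.tsv")
    write_matrix_tsv(mixed, f)
    note("expression", f)
  })

  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(stage = character(), file = character(), md5 = character())
  mf <- file.path(config$outdir, "manifest.tsv")
  write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
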