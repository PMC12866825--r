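## End-to-end orchestration: simulate -> decompose -> call DMRs/DhMRs
## -> enrichment -> dynamics summaries -> reactivation screen, with a
## provenance manifest (md5 checksums) over every produced file.

.log_stage <- function(stage, ..., level = "info", log_level = "info") {
  if (log_level == "quiet" && level == "info") return(invisible())
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.known_config_keys <- c("seed", "out_dir", "log_level", "generator",
                        "caller", "screen")

#' Canonical demo configuration
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A validated pipeline config list (keys: `seed`, `out_dir`,
#'   `log_level`, `generator`, `caller`, `screen`).
#' @export
demo_config <- function(seed = 17L, out_dir = "hydroxydyn_demo") {
  list(seed = as.integer(seed), out_dir = out_dir, log_level = "info",
       generator = list(), caller = list(), screen = list())
}

.validate_config <- function(config) {
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 17L)
  config$out_dir <- config$out_dir %||% "hydroxydyn_run"
  config$log_level <- config$log_level %||% "info"
  config$generator <- config$generator %||% list()
  config$caller <- config$caller %||% list()
  config$screen <- config$screen %||% list()
  gen_ok <- names(formals(truth_config))
  unknown <- setdiff(names(config$generator), gen_ok)
  if (length(unknown))
    stop("unknown generator key(s): ", paste(unknown, collapse = ", "))
  ## reject invalid generator values before any stage runs
  do.call(truth_config, c(config$generator, list(seed = config$seed)))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline on generated data
#'
#' Simulates a methylome study from the generator defaults (plus any
#' `config$generator` overrides), decomposes paired BS/ACE counts into
#' 5mC/5hmC level tracks, calls methylation DMRs (SCNT vs WT 2-cell)
#' and hydroxymethylation dynamics (MEF -> SCNT 2-cell), scores element
#' enrichment of the gain DhMRs, computes the delta-5mC/delta-5hmC
#' correlation over the planted coupling regions, the X-vs-autosome
#' 5hmC comparison, the gICR panel, the OE-vs-control DhMR/DMR contrast
#' and the reactivation screen (on an engineered fixture), writing each
#' stage's outputs plus `manifest.json` with md5 checksums of every
#' produced file.
#'
#' @param config Pipeline config (see [demo_config()]); unknown keys
#'   are rejected before any stage runs.
#' @return Invisibly, a list with the out_dir, the manifest and the
#'   per-stage summary list.
#' @export
run_pipeline <- function(config = demo_config()) {
  config <- .validate_config(config)
  out_dir <- config$out_dir
  ll <- config$log_level
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config_echo.yaml"))
  summaries <- list()

  .log_stage("simulate", "generating synthetic methylomes", log_level = ll)
  cfg <- do.call(truth_config,
                 c(config$generator, list(seed = config$seed)))
  sim <- simulate_counts(cfg)
  write_chrom_sizes(sim$genome, file.path(out_dir, "chrom.sizes"))
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(ann_dir, showWarnings = FALSE)
  for (nm in c("promoters", "enhancers", "gicr", "planted", "coupling"))
    if (!is.null(sim$annotations[[nm]]) && nrow(sim$annotations[[nm]]))
      write_bed(sim$annotations[[nm]],
                file.path(ann_dir, paste0(nm, ".bed")))
  summaries$simulate <- list(n_cpg = nrow(sim$cpg),
                             n_tracks = length(sim$tracks),
                             seed = cfg$seed)

  .log_stage("decompose", "MLE decomposition of BS/ACE pairs",
             log_level = ll)
  need <- sim$samples[sim$samples$sex == "XX" &
                        sim$samples$allele %in%
                        c("maternal", "paternal", "combined"), ]
  levels_m <- list(); levels_h <- list(); conflict <- numeric()
  for (i in seq_len(nrow(need))) {
    sid <- need$sample_id[i]
    dec <- decompose_track(sim$tracks[[paste0(sid, "|BS")]],
                           sim$tracks[[paste0(sid, "|ACE")]])
    levels_m[[sid]] <- dec$level_m
    levels_h[[sid]] <- dec$level_h
    conflict[sid] <- dec$conflict_fraction
  }
  summaries$decompose <- list(n_samples = length(conflict),
                              mean_conflict_fraction =
                                mean(conflict, na.rm = TRUE))

  pick <- function(group, allele = "maternal") {
    ids <- need$sample_id[need$group == group & need$allele == allele]
    list(m = levels_m[ids], h = levels_h[ids])
  }

  .log_stage("dmr", "methylation DMRs: SCNT_2C vs WT_2C", log_level = ll)
  pm <- do.call(caller_params,
                c(list(mode = "methylation"), config$caller))
  dmrs_m <- call_dmrs(pick("SCNT_2C")$m, pick("WT_2C")$m,
                      sim$genome, pm)
  write_regions(dmrs_m, file.path(out_dir, "dmrs_methylation.bed"))

  .log_stage("dmr", "hydroxymethylation dynamics: MEF -> SCNT_2C",
             log_level = ll)
  ph <- do.call(caller_params,
                c(list(mode = "hydroxymethylation"), config$caller))
  dyn <- categorize_dynamics(pick("MEF")$h, pick("SCNT_2C")$h,
                             sim$genome, ph)
  for (nm in names(dyn))
    write_regions(dyn[[nm]],
                  file.path(out_dir, paste0("dhmr_", nm, ".bed")))
  summaries$dmr <- list(
    n_dmr = sum(dmrs_m$region_class %in% c("hyper", "hypo")),
    dynamics = vapply(dyn, nrow, integer(1)))

  .log_stage("enrich", "element enrichment of gain DhMRs", log_level = ll)
  background <- attr(dyn$gain, "tiles")
  if (nrow(dyn$gain) && !is.null(background) && nrow(background)) {
    ## enrichment is computed relative to callable (tiled) territory,
    ## so called extents are clipped to it first
    enr <- enrichment_table(
      clip_regions(dyn$gain, background),
      list(promoter = sim$annotations$promoters,
           enhancer = sim$annotations$enhancers,
           gICR = sim$annotations$gicr),
      background)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summaries$enrich <- list(
      scores = stats::setNames(enr$score, enr$element_name))
  } else {
    summaries$enrich <- list(scores = NULL)
  }

  .log_stage("dynamics", "delta correlation, X summary, gICR panel",
             log_level = ll)
  coup <- sim$annotations$coupling
  deltas <- region_deltas(coup, pick("MEF")$m, pick("MEF")$h,
                          pick("SCNT_2C")$m, pick("SCNT_2C")$h)
  dc <- delta_correlation(deltas)
  xsum <- chromosome_summary(pick("SCNT_2C")$h,
                             sim$annotations$tiles_100kb,
                             sim$genome$x_chrom)
  panel_tracks <- c(unlist(lapply(intersect(cfg$groups,
                                            c("MEF", "SCNT_2C", "SCNT_48C",
                                              "SCNT_blast")),
                                  function(g) c(pick(g, "maternal")$m,
                                                pick(g, "paternal")$m,
                                                pick(g, "maternal")$h,
                                                pick(g, "paternal")$h)),
                           recursive = FALSE))
  panel <- gicr_panel(panel_tracks, sim$annotations$gicr)
  utils::write.table(panel, file.path(out_dir, "gicr_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summaries$dynamics <- list(
    delta_r = dc$r, delta_n = dc$n,
    x_vs_autosome_p = xsum$p_x_vs_autosome,
    x_median = xsum$x_median,
    autosome_median = xsum$autosome_median)

  .log_stage("screen", "OE contrast and reactivation screen",
             log_level = ll)
  if ("OE_2C" %in% cfg$groups) {
    oe_dyn <- categorize_dynamics(pick("SCNT_2C")$h, pick("OE_2C")$h,
                                  sim$genome, ph)
    gain <- oe_dyn$gain
    if (nrow(gain)) {
      ctrl_h <- .aggregate_group(pick("SCNT_2C")$h)
      gain$control_h <- vapply(seq_len(nrow(gain)), function(i)
        .region_mean(ctrl_h, gain$chrom[i], gain$start[i],
                     gain$end[i])[["mean"]], numeric(1))
    }
    oe_dmr <- call_dmrs(pick("OE_2C")$m, pick("SCNT_2C")$m,
                        sim$genome, pm)
    hypo <- oe_dmr[oe_dmr$region_class == "hypo", , drop = FALSE]
    write_regions(gain[, setdiff(names(gain), "control_h")],
                  file.path(out_dir, "oe_gain_dhmrs.bed"))
    write_regions(hypo, file.path(out_dir, "oe_hypo_dmrs.bed"))
    summaries$screen <- list(n_oe_gain = nrow(gain),
                             n_oe_hypo = nrow(hypo))
  }
  sp <- do.call(screen_params, config$screen)
  fx <- simulate_screen_fixture(seed = config$seed, params = sp)
  hits <- reactivation_screen(fx$deg, fx$gain_dhmrs, fx$hypo_dmrs,
                              fx$promoters, sp)
  utils::write.table(hits, file.path(out_dir, "reactivated_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summaries$screen$n_reactivated <- nrow(hits)

  jsonlite::write_json(summaries, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  .log_stage("done", length(files), " files written to ", out_dir,
             log_level = ll)
  invisible(list(out_dir = out_dir, manifest = manifest,
                 summaries = summaries))
}

#' One-command demo on the default toy genome
#'
#' @param out_dir Output directory.
#' @param seed Master seed; two runs with the same seed produce
#'   identical manifests.
#' @return See [run_pipeline()].
#' @export
run_demo <- function(out_dir = "hydroxydyn_demo", seed = 17L) {
  run_pipeline(demo_config(seed = seed, out_dir = out_dir))
}
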