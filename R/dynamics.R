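#' Parameters of the ectopic-5hmC gene-reactivation screen
#'
#' @param deg_p Maximum differential-expression p-value.
#' @param deg_lfc Minimum log2 fold change (treatment over control).
#' @param silent_max_expr Normalized-count ceiling defining "low
#'   expression or silence" in the control group.
#' @param ectopic_h_max Control 5hmC ceiling below which a gain DhMR
#'   counts as ectopically generated (aligned with the caller's
#'   stable-high floor); gain DhMRs at or above it are "enhanced".
#' @param element Which regulatory element links regions to genes:
#'   `"promoter"` or `"enhancer"`.
#' @return A `screen_params` list.
#' @export
screen_params <- function(deg_p = 0.01, deg_lfc = 1.0,
                          silent_max_expr = 5, ectopic_h_max = 0.05,
                          element = c("promoter", "enhancer")) {
  element <- match.arg(element)
  if (any(c(deg_p, deg_lfc, silent_max_expr, ectopic_h_max) < 0))
    stop("screen thresholds must be >= 0")
  structure(list(deg_p = deg_p, deg_lfc = deg_lfc,
                 silent_max_expr = silent_max_expr,
                 ectopic_h_max = ectopic_h_max, element = element),
            class = "screen_params")
}

#' Categorize regions by 5hmC change between two stages
#'
#' Runs the hydroxymethylation caller with the later stage as group A
#' and the earlier stage as group B and splits the retained regions
#' into `gain` (hyper: stage 2 above stage 1), `loss` (hypo),
#' `stable_high` and `stable_low`. The four sets are disjoint;
#' swapping the stage order swaps gain and loss exactly.
#'
#' @param tracks_stage1,tracks_stage2 Lists of 5hmC level (or ACE
#'   count) [methylome_track()]s for the earlier / later stage.
#' @param genome A [genome_layout()]; both track sets must be on it.
#' @param params A hydroxymethylation-mode [caller_params()].
#' @return Named list of region data.frames: `gain`, `loss`,
#'   `stable_high`, `stable_low`.
#' @export
categorize_dynamics <- function(tracks_stage1, tracks_stage2, genome,
                                params = caller_params("hydroxymethylation")) {
  if (params$mode != "hydroxymethylation")
    stop("categorize_dynamics requires hydroxymethylation mode")
  chk <- function(tracks) {
    for (tr in tracks)
      if (!all(unique(tr$chrom) %in% genome$chrom_names))
        stop("track chromosome(s) not in the genome layout; ",
             "stage tracks from different genomes?")
  }
  chk(tracks_stage1); chk(tracks_stage2)
  regions <- call_dmrs(tracks_stage2, tracks_stage1, genome, params)
  split_cls <- function(cls)
    regions[regions$region_class == cls, , drop = FALSE]
  list(gain = split_cls("hyper"), loss = split_cls("hypo"),
       stable_high = split_cls("stable_high"),
       stable_low = split_cls("stable_low"))
}

## coverage-weighted mean level of one aggregated track over an interval
.region_mean <- function(agg, chrom, start, end) {
  inr <- agg$chrom == chrom & agg$pos >= start & agg$pos < end
  if (!any(inr)) return(c(mean = NA_real_, n = 0))
  c(mean = sum(agg$level[inr] * agg$w[inr]) / sum(agg$w[inr]),
    n = sum(inr))
}

#' Region-wise changes in 5mC and 5hmC between two stages
#'
#' @param regions Interval data.frame over which deltas are computed.
#' @param m1,h1,m2,h2 Lists of level tracks (5mC and 5hmC for stage 1
#'   and stage 2; replicates are aggregated by coverage-weighted mean).
#' @return data.frame with per-region `d_m` (stage2 - stage1 5mC) and
#'   `d_h`; regions with no covered CpGs in any input get NA.
#' @export
region_deltas <- function(regions, m1, h1, m2, h2) {
  aggs <- lapply(list(m1 = m1, h1 = h1, m2 = m2, h2 = h2),
                 .aggregate_group)
  one <- function(i) {
    v <- vapply(aggs, function(a)
      .region_mean(a, regions$chrom[i], regions$start[i],
                   regions$end[i])[["mean"]], numeric(1))
    c(d_m = v[["m2"]] - v[["m1"]], d_h = v[["h2"]] - v[["h1"]])
  }
  d <- t(vapply(seq_len(nrow(regions)), one, numeric(2)))
  out <- cbind(regions[, c("chrom", "start", "end")],
               d_m = d[, "d_m"], d_h = d[, "d_h"])
  rownames(out) <- NULL
  out
}

#' Pearson correlation between region-wise 5mC and 5hmC changes
#'
#' @param deltas data.frame with `d_m` and `d_h` (see
#'   [region_deltas()]); rows with NA in either delta are dropped.
#' @return list with `r` (Pearson correlation coefficient), `p`
#'   (correlation-test p-value) and `n` (regions used).
#' @export
delta_correlation <- function(deltas) {
  ok <- stats::complete.cases(deltas[, c("d_m", "d_h")])
  d <- deltas[ok, ]
  if (nrow(d) < 3)
    stop("delta_correlation needs at least 3 regions with both deltas")
  ct <- stats::cor.test(d$d_m, d$d_h, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}

#' Chromosome-wise tile summary with an X-vs-autosome test
#'
#' Averages a level track within precomputed tiles (e.g. 100-kb),
#' reports the median tile level per chromosome, and compares X-tile
#' levels against pooled autosomal tile levels with a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param tracks A level track or list of replicate level tracks.
#' @param tiles Tile intervals (e.g. `tile_genome(genome, 1e5)`).
#' @param x_chrom Name of the X chromosome.
#' @return list with `tile_levels` (per-tile means), `per_chrom`
#'   (median per chromosome), `p_x_vs_autosome` and the median levels
#'   `x_median` / `autosome_median`.
#' @export
chromosome_summary <- function(tracks, tiles, x_chrom) {
  agg <- .aggregate_group(tracks)
  dt <- data.table::data.table(chrom = agg$chrom, pos = agg$pos,
                               level = agg$level)
  tl <- data.table::data.table(chrom = tiles$chrom, start = tiles$start,
                               end = tiles$end)
  tl$tile_id <- seq_len(nrow(tl))
  dt$start <- dt$pos; dt$end <- dt$pos + 1
  data.table::setkeyv(tl, c("chrom", "start", "end"))
  ov <- data.table::foverlaps(dt, tl, type = "within", nomatch = NULL)
  means <- ov[, list(level = mean(level), n_cpg = .N), by = "tile_id"]
  out <- merge(as.data.frame(tl), as.data.frame(means), by = "tile_id")
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  x_lv <- out$level[out$chrom == x_chrom]
  a_lv <- out$level[out$chrom != x_chrom]
  if (!length(x_lv)) stop("no covered tiles on the X chromosome")
  if (!length(a_lv)) stop("no covered autosomal tiles")
  wt <- stats::wilcox.test(x_lv, a_lv, alternative = "two.sided",
                           exact = FALSE)
  per_chrom <- stats::aggregate(level ~ chrom, data = out, FUN = stats::median)
  list(tile_levels = out, per_chrom = per_chrom,
       p_x_vs_autosome = wt$p.value,
       x_median = stats::median(x_lv),
       autosome_median = stats::median(a_lv))
}

#' Mean modification levels at gICRs per allele and stage
#'
#' Coverage-weighted mean 5mC and/or 5hmC level of every germline
#' imprinting control region in each supplied track; regions with no
#' covered CpG in a track are reported as absent (no row), never as
#' zero.
#'
#' @param tracks Named list of level [methylome_track()]s (each carries
#'   its group/allele metadata and `level_m` / `level_h` state).
#' @param gicr gICR interval data.frame with a `gicr_id` column.
#' @return Long data.frame: `gicr_id`, `group`, `sex`, `allele`,
#'   `state`, `mean_level`, `n_cpg`.
#' @export
gicr_panel <- function(tracks, gicr) {
  if (inherits(tracks, "methylome_track")) tracks <- list(tracks)
  rows <- list()
  for (tr in tracks) {
    meta <- attr(tr, "meta")
    df <- as.data.frame(tr)
    w <- if (is.null(df$weight)) rep(1, nrow(df)) else df$weight
    for (i in seq_len(nrow(gicr))) {
      inr <- df$chrom == gicr$chrom[i] & df$pos >= gicr$start[i] &
        df$pos < gicr$end[i]
      if (!any(inr)) next
      rows[[length(rows) + 1]] <- data.frame(
        gicr_id = gicr$gicr_id[i], group = meta$group, sex = meta$sex,
        allele = meta$allele, replicate = meta$replicate,
        state = attr(tr, "assay"),
        mean_level = sum(df$level[inr] * w[inr]) / sum(w[inr]),
        n_cpg = sum(inr))
    }
  }
  if (!length(rows))
    return(data.frame(gicr_id = character(), group = character(),
                      sex = character(), allele = character(),
                      replicate = integer(), state = character(),
                      mean_level = numeric(), n_cpg = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' X-to-autosome expression ratio per sample
#'
#' Sum of normalized counts of X-linked genes divided by the sum over
#' autosomal genes, per sample column.
#'
#' @param expr Matrix or data.frame of normalized counts (rows =
#'   genes, columns = samples) with rownames = gene ids.
#' @param gene_chrom Named character vector mapping gene id ->
#'   chromosome.
#' @param x_chrom Name of the X chromosome.
#' @return Named numeric vector of per-sample X/A ratios.
#' @export
xa_ratio <- function(expr, gene_chrom, x_chrom) {
  expr <- as.matrix(expr)
  chrom <- gene_chrom[rownames(expr)]
  if (anyNA(chrom))
    stop("gene(s) without chromosome assignment: ",
         paste(utils::head(rownames(expr)[is.na(chrom)], 3),
               collapse = ", "))
  x_sum <- colSums(expr[chrom == x_chrom, , drop = FALSE])
  a_sum <- colSums(expr[chrom != x_chrom, , drop = FALSE])
  if (any(a_sum == 0)) stop("zero autosomal expression in some sample")
  x_sum / a_sum
}

#' Screen for genes reactivated by ectopic 5hmC gain
#'
#' Selects genes satisfying both published criteria: (1)
#' transcriptional reactivation - low expression or silence in the
#' control group (`mean_expr_control <= silent_max_expr`) but activated
#' on overexpression (`log2fc >= deg_lfc`, `p <= deg_p`); and (2) the
#' gene's regulatory element (promoter, or linked enhancer) overlaps at
#' least one ectopically generated gain DhMR (control 5hmC
#' `< ectopic_h_max`) and at least one hypo DMR from the same contrast.
#'
#' @param deg DEG table: `gene_id`, `log2fc`, `p`,
#'   `mean_expr_control`, `mean_expr_treatment`.
#' @param gain_dhmrs Gain (hyper) DhMRs from the OE-vs-control run with
#'   a `control_h` column (mean 5hmC of the region in the control
#'   group).
#' @param hypo_dmrs Hypo DMRs from the same contrast in methylation
#'   mode.
#' @param elements Element intervals carrying `gene_id` (promoters, or
#'   enhancers after [assign_enhancers_to_genes()]).
#' @param params A [screen_params()].
#' @return data.frame of selected genes with their expression evidence
#'   and the number of supporting ectopic DhMRs / hypo DMRs per gene;
#'   attribute `"evidence"` holds the full per-gene criterion table.
#' @export
reactivation_screen <- function(deg, gain_dhmrs, hypo_dmrs, elements,
                                params = screen_params()) {
  if (is.null(gain_dhmrs$control_h))
    stop("gain_dhmrs must carry a control_h column")
  if (is.null(elements$gene_id))
    stop("elements must carry gene_id (promoters, or enhancers after ",
         "assign_enhancers_to_genes())")
  ectopic <- gain_dhmrs[gain_dhmrs$control_h < params$ectopic_h_max, ,
                        drop = FALSE]
  count_hits <- function(set) {
    if (!nrow(set) || !nrow(elements))
      return(integer(nrow(elements)))
    IRanges::countOverlaps(.as_gr(elements), .as_gr(set))
  }
  el <- elements
  el$n_ectopic <- count_hits(ectopic)
  el$n_hypo <- count_hits(hypo_dmrs)
  per_gene <- stats::aggregate(
    cbind(n_ectopic, n_hypo) ~ gene_id, data = el, FUN = sum)
  ev <- merge(deg, per_gene, by = "gene_id", all.x = TRUE)
  ev$n_ectopic[is.na(ev$n_ectopic)] <- 0L
  ev$n_hypo[is.na(ev$n_hypo)] <- 0L
  ev$silent_ok <- ev$mean_expr_control <= params$silent_max_expr
  ev$activated_ok <- ev$log2fc >= params$deg_lfc & ev$p <= params$deg_p
  ev$element_ok <- ev$n_ectopic >= 1 & ev$n_hypo >= 1
  ev$selected <- ev$silent_ok & ev$activated_ok & ev$element_ok
  out <- ev[ev$selected,
            c("gene_id", "log2fc", "p", "mean_expr_control",
              "mean_expr_treatment", "n_ectopic", "n_hypo"),
            drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "evidence") <- ev
  out
}
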