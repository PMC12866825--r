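#' Total overlapping base pairs between two interval sets
#'
#' Both inputs are reduced (self-overlaps merged) before intersection,
#' so the result is symmetric and bounded by the total bp of either
#' set.
#'
#' @param regions_a,regions_b Interval data.frames (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @return Total overlapping bp (numeric scalar).
#' @export
overlap_bp <- function(regions_a, regions_b) {
  if (!nrow(regions_a) || !nrow(regions_b)) return(0)
  .check_intervals(regions_a); .check_intervals(regions_b)
  ga <- GenomicRanges::reduce(.as_gr(regions_a))
  gb <- GenomicRanges::reduce(.as_gr(regions_b))
  ov <- GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(ov)))
}

#' Total bp of an interval set (after merging self-overlaps)
#' @param regions Interval data.frame.
#' @return Numeric scalar bp.
#' @export
total_bp <- function(regions) {
  if (!nrow(regions)) return(0)
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(.as_gr(regions)))))
}

#' Clip an interval set to a covering set
#'
#' @param regions,covering Interval data.frames.
#' @return The part of `regions` (merged) lying inside `covering`.
#' @export
clip_regions <- function(regions, covering) {
  if (!nrow(regions) || !nrow(covering)) return(regions[0, c("chrom", "start", "end")])
  .from_gr(GenomicRanges::intersect(
    GenomicRanges::reduce(.as_gr(regions)),
    GenomicRanges::reduce(.as_gr(covering)), ignore.strand = TRUE))
}

#' Fisher cumulative-length enrichment of regions at an element
#'
#' Builds the 2x2 table of cumulative lengths
#' `a = overlap(dmrs, element)`, `b = len(dmrs) - a`,
#' `c = overlap(background, element) - a`,
#' `d = len(background) - len(dmrs) - c`, applies a two-sided Fisher
#' exact test with bp as counts, and reports the enrichment score
#' `-log10(p)`. An optional common down-scaling factor keeps the exact
#' test tractable on large genomes.
#'
#' @param dmrs,element,background Interval data.frames; the background
#'   should cover the regions being tested (a warning is emitted and
#'   the regions and element are clipped to the background when it
#'   does not, so the table margins stay consistent).
#' @param element_name Label carried into the result.
#' @param scale_factor Divide all four cells by this factor (rounded)
#'   before testing; 1 = off.
#' @return One-row data.frame: `element_name`, `dmr_bp_in`,
#'   `dmr_bp_out`, `bg_bp_in`, `bg_bp_out`, `odds_ratio`, `p`, `score`.
#' @export
enrichment_score <- function(dmrs, element, background,
                             element_name = "element",
                             scale_factor = 1) {
  if (!nrow(dmrs)) stop("empty region set")
  if (!nrow(background)) stop("empty background set")
  len_bg <- total_bp(background)
  if (overlap_bp(dmrs, background) < total_bp(dmrs) - 0.5) {
    warning("background does not fully cover the tested regions; ",
            "clipping to the background")
    dmrs <- .from_gr(GenomicRanges::intersect(
      GenomicRanges::reduce(.as_gr(dmrs)), .as_gr(background),
      ignore.strand = TRUE))
    if (!nrow(dmrs)) stop("no tested region bp inside the background")
  }
  len_dmr <- total_bp(dmrs)
  a <- overlap_bp(dmrs, element)
  cc <- overlap_bp(background, element) - a
  b <- len_dmr - a
  dd <- len_bg - len_dmr - cc
  cells <- round(c(a, b, cc, dd) / scale_factor)
  if (any(cells < 0))
    stop("negative contingency cell; element/background inconsistent")
  ft <- fisher_bp_test(cells[1], cells[2], cells[3], cells[4])
  data.frame(element_name = element_name,
             dmr_bp_in = a, dmr_bp_out = b, bg_bp_in = cc,
             bg_bp_out = dd,
             odds_ratio = ft$odds_ratio, p = ft$p,
             score = -log10(ft$p))
}

#' Two-sided Fisher exact test on a 2x2 bp table
#'
#' The test behind [enrichment_score()], exposed so contingency tables
#' can be scored directly.
#'
#' @param a,b,c,d Cell counts (cumulative bp): `a` = region bp inside
#'   the element, `b` = region bp outside, `c` = background-only bp
#'   inside, `d` = background-only bp outside.
#' @return list with `p` (two-sided exact p) and `odds_ratio`
#'   (conditional MLE).
#' @export
fisher_bp_test <- function(a, b, c, d) {
  ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Enrichment of a region set across a collection of elements
#'
#' @param dmrs Region set to test.
#' @param elements Named list of element interval data.frames.
#' @param background Background interval set.
#' @param scale_factor Passed to [enrichment_score()].
#' @return data.frame with one row per element.
#' @export
enrichment_table <- function(dmrs, elements, background,
                             scale_factor = 1) {
  out <- lapply(names(elements), function(nm)
    enrichment_score(dmrs, elements[[nm]], background,
                     element_name = nm, scale_factor = scale_factor))
  do.call(rbind, out)
}

#' Assign enhancers to their nearest gene
#'
#' Each enhancer is assigned to the gene whose TSS is nearest to the
#' enhancer center, provided that distance is strictly below
#' `max_dist`; equidistant TSSs are broken towards the lower
#' coordinate. Enhancers with no TSS within range remain unassigned
#' (`gene_id = NA`).
#'
#' @param enhancers Interval data.frame (optionally with
#'   `enhancer_id`).
#' @param tss data.frame `chrom`, `pos`, `gene_id`.
#' @param max_dist Maximum center-to-TSS distance in bp (exclusive).
#' @return `enhancers` with `gene_id` and `tss_dist` columns.
#' @export
assign_enhancers_to_genes <- function(enhancers, tss, max_dist = 1e5) {
  if (!nrow(tss)) stop("TSS set is empty")
  center <- floor((enhancers$start + enhancers$end) / 2)
  gene <- rep(NA_character_, nrow(enhancers))
  dist <- rep(NA_real_, nrow(enhancers))
  for (cn in unique(enhancers$chrom)) {
    ti <- which(tss$chrom == cn)
    ei <- which(enhancers$chrom == cn)
    if (!length(ti) || !length(ei)) next
    o <- ti[order(tss$pos[ti])]
    tp <- tss$pos[o]
    for (j in ei) {
      d <- abs(tp - center[j])
      best <- which(d == min(d))[1]  # tp sorted: first = lower coordinate
      if (d[best] < max_dist) {
        gene[j] <- tss$gene_id[o[best]]
        dist[j] <- d[best]
      }
    }
  }
  enhancers$gene_id <- gene
  enhancers$tss_dist <- dist
  enhancers
}

#' Classify enhancers by 5hmC behaviour
#'
#' Partitions enhancers into newly generated 5hmC-associated enhancers
#' (NGE: overlap a gain DhMR only), stable-high 5hmC-associated
#' enhancers (SHE: overlap a stable-high region only), bivalent
#' enhancers (BVE: overlap both) and `other` (neither). The four
#' classes partition the input.
#'
#' @param enhancers Enhancer interval data.frame.
#' @param gain_dhmrs,stable_high_regions Region sets from the
#'   hydroxymethylation caller.
#' @return `enhancers` with an `enhancer_class` column.
#' @export
classify_enhancer_5hmc <- function(enhancers, gain_dhmrs,
                                   stable_high_regions) {
  hits <- function(set) {
    if (!nrow(set) || !nrow(enhancers)) return(rep(FALSE, nrow(enhancers)))
    IRanges::overlapsAny(.as_gr(enhancers), .as_gr(set))
  }
  g <- hits(gain_dhmrs)
  s <- hits(stable_high_regions)
  enhancers$enhancer_class <- ifelse(g & s, "BVE",
                               ifelse(g, "NGE",
                               ifelse(s, "SHE", "other")))
  enhancers
}
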