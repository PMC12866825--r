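#' Parameters of the window-based differential caller
#'
#' Defaults follow the published procedure: 100-bp tiles retained with
#' >= 2 CpGs; 1000-bp windows advanced by 300 bp; Student's t-tests on
#' per-CpG levels; overlapping windows with p < 0.1 merged; methylation
#' mode classifies |diff| > 0.25 as hyper/hypo and |diff| < 0.15 with
#' both group means > 0.65 as stable-high; hydroxymethylation mode uses
#' |diff| > 0.03 and a 0.05 stable-high floor (with the complementary
#' stable-low class); same-class regions within 10 kb are merged;
#' retained differential regions need >= 3 CpGs and BH-adjusted q < 0.1,
#' stable regions q > 0.05.
#'
#' @param mode `"methylation"` or `"hydroxymethylation"`.
#' @param tile_bp,min_cpg_tile Tiling width and CpG floor per tile.
#' @param window_bp,step_bp Sliding-window geometry.
#' @param merge_p Window p-value threshold for merging.
#' @param diff_hyper Group-difference threshold for hyper/hypo.
#' @param stable_diff,stable_floor Stable-class |diff| ceiling and
#'   per-group mean floor.
#' @param same_class_gap Max gap (bp) for same-class merging.
#' @param min_cpg_region Minimum CpGs for a differential region.
#' @param region_q,stable_q FDR thresholds (differential: q < region_q;
#'   stable: q > stable_q).
#' @param stable_q_direction `"greater"` keeps stable regions with
#'   q > stable_q (non-significant loci); `"less"` selects the
#'   alternative reading q < stable_q.
#' @return A `caller_params` list.
#' @export
caller_params <- function(mode = c("methylation", "hydroxymethylation"),
                          tile_bp = 100, min_cpg_tile = 2,
                          window_bp = 1000, step_bp = 300,
                          merge_p = 0.1,
                          diff_hyper = NULL, stable_diff = NULL,
                          stable_floor = NULL,
                          same_class_gap = 10000, min_cpg_region = 3,
                          region_q = 0.1, stable_q = 0.05,
                          stable_q_direction = c("greater", "less")) {
  mode <- match.arg(mode)
  stable_q_direction <- match.arg(stable_q_direction)
  if (step_bp > window_bp) stop("step_bp must be <= window_bp")
  if (is.null(diff_hyper))
    diff_hyper <- if (mode == "methylation") 0.25 else 0.03
  if (is.null(stable_diff))
    stable_diff <- if (mode == "methylation") 0.15 else 0.03
  if (is.null(stable_floor))
    stable_floor <- if (mode == "methylation") 0.65 else 0.05
  thr <- c(diff_hyper, stable_diff, stable_floor, merge_p,
           region_q, stable_q)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(mode = mode, tile_bp = tile_bp,
                 min_cpg_tile = min_cpg_tile, window_bp = window_bp,
                 step_bp = step_bp, merge_p = merge_p,
                 diff_hyper = diff_hyper, stable_diff = stable_diff,
                 stable_floor = stable_floor,
                 same_class_gap = same_class_gap,
                 min_cpg_region = min_cpg_region, region_q = region_q,
                 stable_q = stable_q,
                 stable_q_direction = stable_q_direction),
            class = "caller_params")
}

## aggregate replicate tracks of one group per CpG.
## count tracks: sum k / sum n; level tracks: coverage-weighted mean.
.aggregate_group <- function(tracks) {
  if (inherits(tracks, "methylome_track")) tracks <- list(tracks)
  if (!length(tracks)) stop("empty track list")
  is_count <- vapply(tracks, function(t)
    attr(t, "assay") %in% c("BS", "ACE"), logical(1))
  if (!all(is_count) && any(is_count))
    stop("cannot mix count and level tracks within a group")
  dt <- data.table::rbindlist(lapply(tracks, function(t) {
    df <- as.data.frame(t)
    if (attr(t, "assay") %in% c("BS", "ACE")) {
      data.table::data.table(chrom = df$chrom, pos = df$pos,
                             num = df$k, w = df$n)
    } else {
      w <- if (is.null(df$weight)) rep(1, nrow(df)) else df$weight
      data.table::data.table(chrom = df$chrom, pos = df$pos,
                             num = df$level * w, w = w)
    }
  }))
  agg <- dt[, list(num = sum(num), w = sum(w)), by = c("chrom", "pos")]
  agg <- agg[agg$w > 0, ]
  agg$level <- agg$num / agg$w
  data.table::setorderv(agg, c("chrom", "pos"))
  as.data.frame(agg[, c("chrom", "pos", "level", "w")])
}

## join the two group aggregates on shared covered CpGs
.paired_sites <- function(tracks_a, tracks_b) {
  a <- .aggregate_group(tracks_a)
  b <- .aggregate_group(tracks_b)
  key_a <- paste(a$chrom, a$pos)
  idx <- match(key_a, paste(b$chrom, b$pos))
  keep <- !is.na(idx)
  data.frame(chrom = a$chrom[keep], pos = a$pos[keep],
             la = a$level[keep], lb = b$level[idx[keep]])
}

## classic equal-variance two-sample t p-value from per-site levels;
## zero-pooled-variance windows: p = 1 when means agree, 0 otherwise
.student_t_p <- function(ma, mb, va, vb, na, nb) {
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  d <- ma - mb
  p <- ifelse(se > 0,
              2 * stats::pt(-abs(d / ifelse(se > 0, se, 1)),
                            df = na + nb - 2),
              ifelse(abs(d) <= 1e-12, 1, 0))
  p
}

#' Tile the genome and keep CpG-dense tiles
#'
#' Non-overlapping `tile_bp` tiles that contain at least `min_cpg_tile`
#' CpG sites; the last tile of a chromosome is truncated at its end.
#'
#' @param genome A [genome_layout()].
#' @param cpg_sites data.frame with `chrom`, `pos` of (usable) CpGs.
#' @param tile_bp,min_cpg_tile Tiling parameters.
#' @return data.frame `chrom`, `start`, `end`, `n_cpg` of retained
#'   tiles.
#' @export
tile_and_filter <- function(genome, cpg_sites, tile_bp = 100,
                            min_cpg_tile = 2) {
  if (!nrow(cpg_sites))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_cpg = integer()))
  dt <- data.table::data.table(chrom = cpg_sites$chrom,
                               tile = floor(cpg_sites$pos / tile_bp))
  cnt <- dt[, list(n_cpg = .N), by = c("chrom", "tile")]
  cnt <- cnt[cnt$n_cpg >= min_cpg_tile, ]
  out <- data.frame(chrom = cnt$chrom, start = cnt$tile * tile_bp,
                    end = (cnt$tile + 1) * tile_bp,
                    n_cpg = cnt$n_cpg)
  out$end <- pmin(out$end, genome$chrom_sizes[out$chrom])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## visible sites = paired sites falling inside retained tiles
.visible_sites <- function(sites, tiles, tile_bp) {
  if (!nrow(sites) || !nrow(tiles)) return(sites[0, , drop = FALSE])
  key <- paste(sites$chrom, floor(sites$pos / tile_bp))
  tkey <- paste(tiles$chrom, floor(tiles$start / tile_bp))
  sites[key %in% tkey, , drop = FALSE]
}

## region-level statistics recomputed from visible per-CpG levels;
## per-chromosome sorted cumulative sums keep this O((n + R) log n)
.region_stats <- function(regions, sites) {
  if (!nrow(regions)) {
    regions$mean_a <- regions$mean_b <- regions$diff <- numeric()
    regions$p <- numeric(); regions$n_cpg <- integer()
    return(regions)
  }
  n_r <- nrow(regions)
  ma <- mb <- pv <- rep(NA_real_, n_r)
  ncp <- integer(n_r)
  for (cn in unique(regions$chrom)) {
    s <- sites[sites$chrom == cn, ]
    ri <- which(regions$chrom == cn)
    if (!nrow(s)) next
    s <- s[order(s$pos), ]
    ca <- cumsum(s$la); ca2 <- cumsum(s$la^2)
    cb <- cumsum(s$lb); cb2 <- cumsum(s$lb^2)
    lo <- findInterval(regions$start[ri] - 0.5, s$pos)
    hi <- findInterval(regions$end[ri] - 0.5, s$pos)
    n <- hi - lo
    sum_at <- function(cs, i) ifelse(i > 0, cs[pmax(i, 1)], 0)
    sa <- sum_at(ca, hi) - sum_at(ca, lo)
    sa2 <- sum_at(ca2, hi) - sum_at(ca2, lo)
    sb <- sum_at(cb, hi) - sum_at(cb, lo)
    sb2 <- sum_at(cb2, hi) - sum_at(cb2, lo)
    ok <- n > 0
    ma[ri[ok]] <- sa[ok] / n[ok]
    mb[ri[ok]] <- sb[ok] / n[ok]
    ncp[ri] <- as.integer(n)
    two <- n >= 2
    if (any(two)) {
      va <- pmax(sa2[two] - n[two] * (sa[two] / n[two])^2, 0) / (n[two] - 1)
      vb <- pmax(sb2[two] - n[two] * (sb[two] / n[two])^2, 0) / (n[two] - 1)
      pv[ri[two]] <- .student_t_p(sa[two] / n[two], sb[two] / n[two],
                                  va, vb, n[two], n[two])
    }
  }
  regions$mean_a <- ma; regions$mean_b <- mb
  regions$diff <- ma - mb
  regions$p <- pv; regions$n_cpg <- ncp
  regions
}

#' Score sliding windows by a Student's t-test on per-CpG levels
#'
#' Windows of `window_bp` advanced by `step_bp` over the retained-tile
#' territory; in each window the per-CpG levels of group A are compared
#' with those of group B by a classic (equal-variance) two-sample
#' t-test. Windows with fewer than 2 usable CpGs are skipped;
#' zero-variance windows with equal means score p = 1 (and p = 0 when
#' the means differ).
#'
#' @param sites Paired per-CpG group levels (columns `chrom`, `pos`,
#'   `la`, `lb`), e.g. from aggregated replicate tracks.
#' @param tiles Retained tiles from [tile_and_filter()].
#' @param genome A [genome_layout()].
#' @param params A [caller_params()].
#' @return data.frame of scored windows: `chrom`, `start`, `end`,
#'   `mean_a`, `mean_b`, `diff`, `p`, `n_cpg`.
#' @export
sliding_window_test <- function(sites, tiles, genome, params) {
  vis <- .visible_sites(sites, tiles, params$tile_bp)
  out <- lapply(unique(vis$chrom), function(cn) {
    s <- vis[vis$chrom == cn, ]
    s <- s[order(s$pos), ]
    sz <- genome$chrom_sizes[[cn]]
    starts <- seq(0, max(0, sz - 1), by = params$step_bp)
    ends <- pmin(starts + params$window_bp, sz)
    ## cumulative sums over sorted site levels for O(1) window stats
    ca <- cumsum(s$la); ca2 <- cumsum(s$la^2)
    cb <- cumsum(s$lb); cb2 <- cumsum(s$lb^2)
    lo <- findInterval(starts - 0.5, s$pos)        # sites before window
    hi <- findInterval(ends - 0.5, s$pos)          # sites before end
    n <- hi - lo
    keep <- n >= 2
    if (!any(keep)) return(NULL)
    lo <- lo[keep]; hi <- hi[keep]; n <- n[keep]
    sum_at <- function(cs, i) ifelse(i > 0, cs[pmax(i, 1)], 0)
    sa <- sum_at(ca, hi) - sum_at(ca, lo)
    sa2 <- sum_at(ca2, hi) - sum_at(ca2, lo)
    sb <- sum_at(cb, hi) - sum_at(cb, lo)
    sb2 <- sum_at(cb2, hi) - sum_at(cb2, lo)
    ma <- sa / n; mb <- sb / n
    va <- pmax(sa2 - n * ma^2, 0) / (n - 1)
    vb <- pmax(sb2 - n * mb^2, 0) / (n - 1)
    data.frame(chrom = cn, start = starts[keep], end = ends[keep],
               mean_a = ma, mean_b = mb, diff = ma - mb,
               p = .student_t_p(ma, mb, va, vb, n, n),
               n_cpg = as.integer(n))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mean_a = numeric(),
                      mean_b = numeric(), diff = numeric(),
                      p = numeric(), n_cpg = integer())
  rownames(out) <- NULL
  out
}

#' Merge overlapping significant windows into candidate regions
#'
#' Windows with `p < merge_p` are merged wherever their genomic extents
#' overlap; the statistics of each merged region are recomputed from
#' the underlying per-CpG levels over the merged extent.
#'
#' @param windows Scored windows from [sliding_window_test()].
#' @param sites Paired per-CpG levels (visible sites).
#' @param merge_p Significance threshold for entering a merge.
#' @return data.frame of candidate regions with recomputed `mean_a`,
#'   `mean_b`, `diff`, `p`, `n_cpg`.
#' @export
merge_significant_windows <- function(windows, sites, merge_p = 0.1) {
  sig <- windows[!is.na(windows$p) & windows$p < merge_p, , drop = FALSE]
  if (!nrow(sig))
    return(.region_stats(data.frame(chrom = character(),
                                    start = numeric(), end = numeric()),
                         sites))
  merged <- lapply(unique(sig$chrom), function(cn) {
    s <- sig[sig$chrom == cn, ]
    s <- s[order(s$start, s$end), ]
    st <- s$start[1]; en <- s$end[1]
    res <- list()
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] < en) {
        en <- max(en, s$end[i])
      } else {
        res[[length(res) + 1]] <- c(st, en)
        st <- s$start[i]; en <- s$end[i]
      }
    }
    res[[length(res) + 1]] <- c(st, en)
    m <- do.call(rbind, res)
    data.frame(chrom = cn, start = m[, 1], end = m[, 2])
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  .region_stats(out, sites)
}

#' Classify candidate regions by difference and level thresholds
#'
#' Methylation mode: `diff > diff_hyper` is hyper, `diff < -diff_hyper`
#' hypo, `|diff| < stable_diff` with both group means `> stable_floor`
#' stable-high; anything else is `none`. Hydroxymethylation mode adds
#' the complementary stable-low class (`|diff| < diff threshold`, both
#' means `<= stable_floor`).
#'
#' @param regions Candidate regions with `mean_a`, `mean_b`, `diff`.
#' @param params A [caller_params()].
#' @return `regions` with a `region_class` column.
#' @export
classify_regions <- function(regions, params) {
  d <- regions$diff
  ma <- regions$mean_a; mb <- regions$mean_b
  cls <- rep("none", nrow(regions))
  cls[d > params$diff_hyper] <- "hyper"
  cls[d < -params$diff_hyper] <- "hypo"
  stable <- abs(d) < params$stable_diff
  cls[cls == "none" & stable & ma > params$stable_floor &
        mb > params$stable_floor] <- "stable_high"
  if (params$mode == "hydroxymethylation")
    cls[cls == "none" & stable & ma <= params$stable_floor &
          mb <= params$stable_floor] <- "stable_low"
  regions$region_class <- cls
  regions
}

#' Merge nearby regions of the same class
#'
#' Same-chromosome, same-class regions whose gap is at most
#' `same_class_gap` bp are merged and their statistics recomputed; the
#' operation is idempotent.
#'
#' @param regions Classified regions.
#' @param sites Paired per-CpG levels used to recompute statistics.
#' @param params A [caller_params()].
#' @return Merged, re-scored, re-labelled regions (class labels are
#'   preserved from the inputs being merged).
#' @export
merge_same_class <- function(regions, sites, params) {
  if (!nrow(regions)) return(regions)
  gap <- params$same_class_gap
  parts <- split(regions,
                 paste(regions$chrom, regions$region_class, sep = "\r"))
  merged <- lapply(parts, function(s) {
    s <- s[order(s$start, s$end), ]
    st <- s$start[1]; en <- s$end[1]
    res <- list()
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] - en <= gap) {
        en <- max(en, s$end[i])
      } else {
        res[[length(res) + 1]] <- c(st, en)
        st <- s$start[i]; en <- s$end[i]
      }
    }
    res[[length(res) + 1]] <- c(st, en)
    m <- do.call(rbind, res)
    data.frame(chrom = s$chrom[1], start = m[, 1], end = m[, 2],
               region_class = s$region_class[1])
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  cls <- out$region_class
  out <- .region_stats(out[, c("chrom", "start", "end")], sites)
  out$region_class <- cls
  out
}

#' Apply FDR control and retention rules
#'
#' Benjamini-Hochberg adjustment across all candidate regions;
#' hyper/hypo regions are retained when they contain at least
#' `min_cpg_region` CpGs and reach `q < region_q`; stable classes are
#' retained when `q > stable_q` (loci without significant differences).
#'
#' @param regions Classified, merged candidate regions.
#' @param params A [caller_params()].
#' @return Retained regions (differential + stable) with `q`; the full
#'   scored candidate set is attached as attribute `"candidates"`.
#' @export
finalize_regions <- function(regions, params) {
  if (!nrow(regions)) {
    regions$q <- numeric()
    attr(regions, "candidates") <- regions
    return(regions)
  }
  regions$q <- stats::p.adjust(regions$p, method = "BH")
  is_diff <- regions$region_class %in% c("hyper", "hypo")
  is_stable <- regions$region_class %in% c("stable_high", "stable_low")
  keep_diff <- is_diff & regions$n_cpg >= params$min_cpg_region &
    !is.na(regions$q) & regions$q < params$region_q
  stable_ok <- if (params$stable_q_direction == "greater")
    regions$q > params$stable_q else regions$q < params$stable_q
  keep_stable <- is_stable & !is.na(regions$q) & stable_ok
  out <- regions[keep_diff | keep_stable, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "candidates") <- regions
  out
}

#' Call differentially (hydroxy)methylated regions between two groups
#'
#' Full pipeline: aggregate replicates per group (count tracks by
#' summing k and n per CpG, level tracks by coverage-weighted means),
#' keep 100-bp tiles with >= 2 usable CpGs, score 1000-bp/300-bp
#' sliding windows with Student's t-tests on per-CpG levels, merge
#' overlapping windows with p < 0.1, classify by difference thresholds,
#' merge same-class regions within 10 kb, and retain regions under
#' BH-FDR control.
#'
#' @param tracks_a,tracks_b Lists of [methylome_track()]s (the
#'   replicates of groups A and B).
#' @param genome A [genome_layout()].
#' @param params A [caller_params()].
#' @return Region data.frame (see [finalize_regions()]); attributes
#'   `"candidates"`, `"windows"`, `"tiles"` and `"sites"` expose the
#'   intermediate stages.
#' @export
call_dmrs <- function(tracks_a, tracks_b, genome,
                      params = caller_params()) {
  sites <- .paired_sites(tracks_a, tracks_b)
  tiles <- tile_and_filter(genome, sites, params$tile_bp,
                           params$min_cpg_tile)
  vis <- .visible_sites(sites, tiles, params$tile_bp)
  windows <- sliding_window_test(sites, tiles, genome, params)
  cand <- merge_significant_windows(windows, vis, params$merge_p)
  cand <- classify_regions(cand, params)
  cand <- merge_same_class(cand, vis, params)
  out <- finalize_regions(cand, params)
  attr(out, "windows") <- windows
  attr(out, "tiles") <- tiles
  attr(out, "sites") <- vis
  out
}
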