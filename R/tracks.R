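#' Sample metadata for a methylome track
#'
#' @param sample_id Unique sample identifier string.
#' @param group Biological group, one of the study groups (e.g. `"MEF"`,
#'   `"SCNT_2C"`, `"SCNT_48C"`, `"SCNT_blast"`, `"WT_2C"`, `"WT_48C"`,
#'   `"WT_blast"`, `"OE_2C"`, `"gamete_sperm"`, `"gamete_oocyte"`).
#' @param sex `"XX"` or `"XY"`.
#' @param allele `"maternal"`, `"paternal"` or `"combined"`.
#' @param replicate Replicate index (integer >= 1).
#' @return A `sample_meta` list.
#' @export
sample_meta <- function(sample_id, group = "MEF", sex = "XY",
                        allele = "combined", replicate = 1L) {
  sex <- match.arg(sex, c("XX", "XY"))
  allele <- match.arg(allele, c("maternal", "paternal", "combined"))
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) stop("replicate must be >= 1")
  structure(list(sample_id = as.character(sample_id),
                 group = as.character(group), sex = sex,
                 allele = allele, replicate = replicate),
            class = "sample_meta")
}

#' Per-CpG methylome track
#'
#' A `methylome_track` couples an ordered per-CpG site table with sample
#' metadata and an assay/state label. Count tracks (`assay` `"BS"` or
#' `"ACE"`) carry columns `chrom`, `pos`, `n` (coverage) and `k`
#' (non-converted reads, `0 <= k <= n`). Level tracks (`"level_m"`,
#' `"level_h"`, `"level_u"`) carry `chrom`, `pos`, `level` in `[0, 1]`
#' and optionally `weight` (coverage used to weight region means).
#' Positions are 0-based plus-strand CpG cytosines, strictly increasing
#' within each chromosome.
#'
#' @param sites A data.frame of sites as described above.
#' @param meta A [sample_meta()].
#' @param assay One of `"BS"`, `"ACE"`, `"level_m"`, `"level_h"`,
#'   `"level_u"`.
#' @return A `methylome_track`: the site data.frame with attributes
#'   `meta` and `assay`.
#' @export
methylome_track <- function(sites, meta, assay) {
  assay <- match.arg(assay, c("BS", "ACE", "level_m", "level_h", "level_u"))
  sites <- as.data.frame(sites)
  is_count <- assay %in% c("BS", "ACE")
  need <- if (is_count) c("chrom", "pos", "n", "k") else c("chrom", "pos", "level")
  if (!all(need %in% names(sites)))
    stop("track sites must have columns: ", paste(need, collapse = ", "))
  if (nrow(sites)) {
    if (is_count) {
      if (any(sites$n < 0)) stop("coverage n must be >= 0")
      if (any(sites$k < 0 | sites$k > sites$n))
        stop("non-converted count k must satisfy 0 <= k <= n")
    } else {
      ok <- is.na(sites$level) | (sites$level >= 0 & sites$level <= 1)
      if (!all(ok)) stop("levels must lie in [0, 1]")
    }
    o <- order(sites$chrom, sites$pos)
    sites <- sites[o, , drop = FALSE]
    rownames(sites) <- NULL
    dup <- stats::ave(sites$pos, sites$chrom,
                      FUN = function(p) c(1, diff(p)))
    if (any(dup <= 0))
      stop("positions must be strictly increasing within a chromosome")
  }
  structure(sites, meta = meta, assay = assay,
            class = c("methylome_track", "data.frame"))
}

#' @export
print.methylome_track <- function(x, ...) {
  m <- attr(x, "meta")
  cat("methylome_track [", attr(x, "assay"), "] ", m$sample_id, " (",
      m$group, ", ", m$sex, ", ", m$allele, ", rep", m$replicate, "): ",
      format(nrow(x), big.mark = ","), " sites\n", sep = "")
  invisible(x)
}

#' @export
track_meta <- function(track) attr(track, "meta")

#' @export
track_assay <- function(track) attr(track, "assay")

#' Read a per-CpG count table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tsv_kn`}{Minimal `chrom start end k n` TSV; `start` is the
#'     0-based CpG position.}
#'   \item{`bedgraph_pct_counts`}{MethylDackel-style bedGraph:
#'     `chrom start end pct k_methylated k_unmethylated`; converted to
#'     `k = k_methylated`, `n = k_methylated + k_unmethylated`.}
#' }
#'
#' @param path Input file path (tab-separated, no header).
#' @param dialect `"tsv_kn"` or `"bedgraph_pct_counts"`.
#' @param meta A [sample_meta()] attached to the returned track.
#' @param assay `"BS"` or `"ACE"`.
#' @return A [methylome_track()] of counts.
#' @export
read_counts <- function(path, dialect = c("tsv_kn", "bedgraph_pct_counts"),
                        meta = sample_meta(basename(path)), assay = "BS") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  ncol_need <- if (dialect == "tsv_kn") 5L else 6L
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    empty <- data.frame(chrom = character(), pos = numeric(),
                        n = numeric(), k = numeric())
    return(methylome_track(empty, meta, assay))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < ncol_need)
  if (length(bad))
    stop("malformed line ", bad[1], " in '", path, "': expected ",
         ncol_need, " tab-separated fields")
  m <- matrix(unlist(lapply(parts, `[`, seq_len(ncol_need))),
              ncol = ncol_need, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(pos)) stop("malformed line ", which(is.na(pos))[1],
                       " in '", path, "': non-numeric start")
  if (dialect == "tsv_kn") {
    k <- as.numeric(m[, 4]); n <- as.numeric(m[, 5])
  } else {
    kM <- as.numeric(m[, 5]); kU <- as.numeric(m[, 6])
    k <- kM; n <- kM + kU
  }
  if (anyNA(k) || anyNA(n))
    stop("malformed count field in '", path, "'")
  bad <- which(k > n | k < 0)
  if (length(bad))
    stop("validation error at line ", bad[1], " in '", path,
         "': k must satisfy 0 <= k <= n")
  methylome_track(data.frame(chrom = m[, 1], pos = pos, n = n, k = k),
                  meta, assay)
}

#' Write a count track
#'
#' @param track A count [methylome_track()].
#' @param path Output path.
#' @param dialect Output dialect, as in [read_counts()].
#' @return `path`, invisibly.
#' @export
write_counts <- function(track, path,
                         dialect = c("tsv_kn", "bedgraph_pct_counts")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(track)
  if (dialect == "tsv_kn") {
    out <- data.frame(df$chrom, df$pos, df$pos + 1, df$k, df$n)
  } else {
    pct <- ifelse(df$n > 0, round(100 * df$k / df$n, 6), 0)
    out <- data.frame(df$chrom, df$pos, df$pos + 1, pct, df$k, df$n - df$k)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a per-CpG level track (bedGraph)
#'
#' Four columns: chrom, 0-based position, position + 1, level. A fifth
#' `weight` column (coverage) is written when present and restored on
#' read.
#'
#' @param track A level [methylome_track()].
#' @param path File path.
#' @return [read_levels()] returns a level [methylome_track()].
#' @export
write_levels <- function(track, path) {
  df <- as.data.frame(track)
  out <- data.frame(df$chrom, df$pos, df$pos + 1, df$level)
  if (!is.null(df$weight)) out$weight <- df$weight
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_levels
#' @param meta,assay Metadata for the returned track.
#' @export
read_levels <- function(path, meta = sample_meta(basename(path)),
                        assay = "level_m") {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  names(df)[1:4] <- c("chrom", "pos", "end", "level")
  sites <- data.frame(chrom = as.character(df$chrom), pos = df$pos,
                      level = df$level)
  if (ncol(df) >= 5) sites$weight <- df[[5]]
  methylome_track(sites, meta, assay)
}

#' Collapse CpG dyad counts onto the plus-strand cytosine
#'
#' Symmetric CpG dyads yield two records: the plus-strand C at `pos` and
#' the minus-strand G at `pos + 1`. Given the set of plus-strand CpG
#' positions, counts observed at `pos + 1` are summed into the record at
#' `pos`. The operation is idempotent: once no record sits at `pos + 1`
#' of a known CpG, a second pass is the identity.
#'
#' @param sites Count data.frame (`chrom`, `pos`, `n`, `k`).
#' @param cpg_positions data.frame (`chrom`, `pos`) of plus-strand CpG
#'   cytosines.
#' @return Collapsed count data.frame, one row per covered CpG.
#' @export
collapse_cpg_dyads <- function(sites, cpg_positions) {
  key_c <- paste(sites$chrom, sites$pos)
  key_g <- paste(sites$chrom, sites$pos - 1)
  cpg_key <- paste(cpg_positions$chrom, cpg_positions$pos)
  is_c <- key_c %in% cpg_key
  is_g <- !is_c & (key_g %in% cpg_key)
  if (any(!is_c & !is_g))
    warning(sum(!is_c & !is_g), " records at positions not matching any ",
            "CpG dyad were dropped")
  anchor <- ifelse(is_c, key_c, key_g)
  keep <- is_c | is_g
  dt <- data.table::data.table(anchor = anchor[keep],
                               chrom = sites$chrom[keep],
                               pos = ifelse(is_c, sites$pos,
                                            sites$pos - 1)[keep],
                               n = sites$n[keep], k = sites$k[keep])
  out <- dt[, list(chrom = chrom[1], pos = pos[1], n = sum(n),
                   k = sum(k)), by = "anchor"]
  out <- as.data.frame(out[order(chrom, pos), c("chrom", "pos", "n", "k")])
  rownames(out) <- NULL
  out
}

#' Construct and validate a region table
#'
#' Regions are 0-based half-open intervals with a class label and the
#' statistics attached by the differential caller.
#'
#' @param chrom,start,end Interval coordinates.
#' @param region_class One of `"hyper"`, `"hypo"`, `"stable_high"`,
#'   `"stable_low"`, `"none"`.
#' @param mean_a,mean_b Per-group mean levels.
#' @param p,q Test p-value and FDR-adjusted p.
#' @param n_cpg Number of usable CpG sites in the region.
#' @return A validated `region` data.frame with column `diff`
#'   (`mean_a - mean_b`).
#' @export
region_table <- function(chrom = character(), start = numeric(),
                         end = numeric(), region_class = character(),
                         mean_a = NA_real_, mean_b = NA_real_,
                         p = NA_real_, q = NA_real_, n_cpg = NA_integer_) {
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   region_class = as.character(region_class),
                   mean_a = mean_a, mean_b = mean_b,
                   diff = mean_a - mean_b, p = p, q = q,
                   n_cpg = as.integer(n_cpg))
  validate_regions(df)
}

#' @rdname region_table
#' @param regions A region data.frame to validate.
#' @export
validate_regions <- function(regions) {
  .check_intervals(regions, what = "region table")
  bad_class <- setdiff(unique(regions$region_class),
                       c("hyper", "hypo", "stable_high", "stable_low", "none"))
  if (length(bad_class))
    stop("unknown region class: ", paste(bad_class, collapse = ", "))
  if (nrow(regions)) {
    d <- regions$mean_a - regions$mean_b
    ok <- is.na(d) | is.na(regions$diff) | abs(d - regions$diff) <= 1e-12
    if (!all(ok)) stop("diff must equal mean_a - mean_b")
    if (any(!is.na(regions$n_cpg) & regions$n_cpg < 0))
      stop("n_cpg must be >= 0")
  }
  regions
}

#' Write / read regions as extended BED
#'
#' Columns: chrom, start, end, class, diff, p, q, n_cpg, mean_a, mean_b.
#' Writing then reading is the identity up to numeric formatting.
#'
#' @param regions A region data.frame (see [region_table()]).
#' @param path File path.
#' @export
write_regions <- function(regions, path) {
  validate_regions(regions)
  out <- data.frame(regions$chrom, regions$start, regions$end,
                    regions$region_class,
                    formatC(regions$diff, digits = 15, format = "g"),
                    formatC(regions$p, digits = 15, format = "g"),
                    formatC(regions$q, digits = 15, format = "g"),
                    regions$n_cpg,
                    formatC(regions$mean_a, digits = 15, format = "g"),
                    formatC(regions$mean_b, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  if (length(readLines(path, n = 1)) == 0)
    return(region_table())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          na.strings = c("NA", "nan"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "numeric",
                                         "numeric", "integer", "numeric",
                                         "numeric"))
  names(df) <- c("chrom", "start", "end", "region_class", "diff", "p",
                 "q", "n_cpg", "mean_a", "mean_b")
  df <- df[, c("chrom", "start", "end", "region_class", "mean_a",
               "mean_b", "diff", "p", "q", "n_cpg")]
  validate_regions(df)
}

#' Write / read a plain annotation BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional
#'   name-like columns (e.g. `gene_id`, `strand`), written in that order.
#' @param path File path.
#' @export
write_bed <- function(df, path) {
  .check_intervals(df, what = "annotation")
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  utils::write.table(df[, c("chrom", "start", "end", extra)], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param extra_cols Names for columns beyond chrom/start/end.
#' @export
read_bed <- function(path, extra_cols = character()) {
  if (length(readLines(path, n = 1)) == 0) {
    df <- data.frame(chrom = character(), start = numeric(),
                     end = numeric())
    for (nm in extra_cols) df[[nm]] <- character()
    return(df)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  if (length(extra_cols))
    names(df)[3 + seq_along(extra_cols)] <- extra_cols
  df
}

#' Derive promoter intervals from TSSs
#'
#' Promoters are defined as 1000 bp upstream and 500 bp downstream of
#' the TSS, strand-aware: `[tss - upstream, tss + downstream)` on the
#' plus strand, mirrored to `[tss - downstream, tss + upstream)` on the
#' minus strand, clipped to chromosome bounds.
#'
#' @param tss data.frame with `chrom`, `pos` (0-based TSS), `strand`
#'   (`"+"`/`"-"`) and optionally `gene_id`.
#' @param genome A [genome_layout()] used for clipping.
#' @param upstream,downstream Extents in bp.
#' @return data.frame of promoter intervals, carrying `gene_id` when
#'   present in the input.
#' @export
make_promoters <- function(tss, genome, upstream = 1000, downstream = 500) {
  if (is.null(tss$strand) || anyNA(tss$strand) ||
      !all(tss$strand %in% c("+", "-")))
    stop("TSS entries must carry strand ('+' or '-')")
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$pos - upstream, tss$pos - downstream)
  end <- ifelse(plus, tss$pos + downstream, tss$pos + upstream)
  start <- pmax(start, 0)
  end <- pmin(end, genome$chrom_sizes[tss$chrom])
  out <- data.frame(chrom = tss$chrom, start = start, end = end)
  if (!is.null(tss$gene_id)) out$gene_id <- tss$gene_id
  out$strand <- tss$strand
  .check_intervals(out, genome, what = "promoters")
  out[order(out$chrom, out$start), , drop = FALSE]
}
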