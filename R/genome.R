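#' Describe a genome as a set of named chromosomes
#'
#' A `genome_layout` is the minimal genome model used throughout the
#' package: chromosome names, their sizes in bp, and which chromosome is
#' the X. All interval operations are 0-based half-open.
#'
#' @param chrom_names Character vector of unique chromosome identifiers.
#' @param chrom_sizes Integer vector of chromosome sizes in bp (> 0),
#'   same length as `chrom_names`.
#' @param x_chrom Identifier of the X chromosome; must be one of
#'   `chrom_names`.
#' @return An object of class `genome_layout` with elements
#'   `chrom_names`, `chrom_sizes` (named) and `x_chrom`.
#' @examples
#' genome_layout(c("chr1", "chrX"), c(2e6, 2e6), "chrX")
#' @export
genome_layout <- function(chrom_names, chrom_sizes, x_chrom) {
  chrom_names <- as.character(chrom_names)
  chrom_sizes <- as.numeric(chrom_sizes)
  if (length(chrom_names) != length(chrom_sizes))
    stop("chrom_names and chrom_sizes must have the same length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("all chromosome sizes must be finite and > 0")
  if (!x_chrom %in% chrom_names)
    stop("x_chrom '", x_chrom, "' is not one of the chromosome names")
  names(chrom_sizes) <- chrom_names
  structure(
    list(chrom_names = chrom_names, chrom_sizes = chrom_sizes,
         x_chrom = as.character(x_chrom)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_names), "chromosomes,",
      format(sum(x$chrom_sizes), big.mark = ","), "bp total; X =",
      x$x_chrom, "\n")
  invisible(x)
}

#' Autosome names of a genome layout
#' @param genome A [genome_layout()].
#' @return Character vector of chromosome names excluding the X.
#' @export
autosomes <- function(genome) {
  setdiff(genome$chrom_names, genome$x_chrom)
}

#' Read / write a two-column chrom.sizes file
#'
#' @param path File path of a tab-separated `chrom<TAB>size` table.
#' @param x_chrom X-chromosome name passed through to [genome_layout()];
#'   defaults to a name containing "X" if exactly one exists.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path, x_chrom = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  if (is.null(x_chrom)) {
    cand <- grep("X", df$chrom, value = TRUE)
    if (length(cand) != 1)
      stop("cannot infer x_chrom from '", path, "'; pass x_chrom explicitly")
    x_chrom <- cand
  }
  genome_layout(df$chrom, df$size, x_chrom)
}

#' @rdname read_chrom_sizes
#' @param genome A [genome_layout()] to write.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(chrom = genome$chrom_names, size = genome$chrom_sizes),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Partition a genome into non-overlapping tiles
#'
#' Tiles are `[i * tile_bp, (i + 1) * tile_bp)`; the last tile of each
#' chromosome is truncated at the chromosome end.
#'
#' @param genome A [genome_layout()].
#' @param tile_bp Tile width in bp (e.g. 100 for caller tiles, 1e5 for
#'   chromosome-level summaries).
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @export
tile_genome <- function(genome, tile_bp) {
  tile_bp <- as.numeric(tile_bp)
  if (!is.finite(tile_bp) || tile_bp <= 0) stop("tile_bp must be > 0")
  out <- lapply(genome$chrom_names, function(cn) {
    sz <- genome$chrom_sizes[[cn]]
    starts <- seq(0, sz - 1, by = tile_bp)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + tile_bp, sz))
  })
  do.call(rbind, out)
}

## internal: interval data.frame (chrom/start/end) <-> GRanges.
## GRanges is 1-based closed; all package APIs are 0-based half-open.
.as_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

.from_gr <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr))
}

## internal: validate a chrom/start/end interval frame
.check_intervals <- function(df, genome = NULL, what = "interval set") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$start >= df$end))
    stop(what, ": all intervals must satisfy start < end")
  if (nrow(df) && any(df$start < 0))
    stop(what, ": negative start coordinate")
  if (!is.null(genome)) {
    if (!all(df$chrom %in% genome$chrom_names))
      stop(what, ": chromosome not in genome layout")
    if (any(df$end > genome$chrom_sizes[df$chrom]))
      stop(what, ": interval exceeds chromosome bounds")
  }
  invisible(df)
}
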