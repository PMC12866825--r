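## Seeded synthetic methylome generator.
##
## The generator emulates the data structure of a stage-resolved,
## allele-resolved embryo methylome study: paired BS/ACE count tracks
## for 2 replicates x group x sex x allele over a small multi-chromosome
## genome including chrX, with planted ground truth (DMRs, DhMRs,
## delta-coupling regions, maternal-gICR hypermethylation, a female-X
## 5hmC deficit) so every downstream stage can be validated against
## known truth.

## run expr with a private RNG stream; global RNG state is untouched
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## stable 32-bit substream seed from a master seed and a string tag
.substream_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 1103 + h) %% 2147480009 + 1)
}

.default_stage_profile <- function() {
  data.frame(stage = c("MEF", "C2", "C48", "blast"),
             m = c(0.75, 0.55, 0.65, 0.40),
             h = c(0.02, 0.06, 0.04, 0.01))
}

.group_stage <- function(group) {
  map <- c(MEF = "MEF", SCNT_2C = "C2", WT_2C = "C2", OE_2C = "C2",
           SCNT_48C = "C48", WT_48C = "C48",
           SCNT_blast = "blast", WT_blast = "blast")
  st <- map[group]
  if (anyNA(st)) stop("no stage mapping for group(s): ",
                      paste(group[is.na(st)], collapse = ", "))
  unname(st)
}

## deterministic interval grids for planted features; every grid
## occupies a distinct residue band modulo 25 kb so features never
## collide with one another
.grid_regions <- function(genome, n, offset, step, width, chroms = NULL) {
  if (is.null(chroms)) chroms <- autosomes(genome)
  i <- seq_len(n) - 1
  chrom <- chroms[(i %% length(chroms)) + 1]
  start <- offset + (i %/% length(chroms)) * step
  df <- data.frame(chrom = chrom, start = start, end = start + width)
  if (any(df$end > genome$chrom_sizes[df$chrom]))
    stop("planted interval grid exceeds chromosome bounds; ",
         "enlarge the genome or reduce n")
  df
}

#' Configuration of the synthetic methylome generator
#'
#' The defaults encode the study structure the generator emulates:
#' a 4-autosome + chrX genome (2 Mb each); CpGs at geometric spacing
#' (mean 100 bp); Poisson coverage (mean 30 per assay); a global
#' "up-down" 5hmC profile and "demethylation - de novo - demethylation"
#' 5mC profile across MEF -> 2-cell -> 4-8-cell -> blastocyst; 1-kb
#' block-level heterogeneity shared across groups of the same stage (so
#' same-stage contrasts are exactly null outside planted regions);
#' planted recovery DMRs (delta m = 0.5 between SCNT and WT 2-cell),
#' planted 5hmC-gain DhMRs, coupling regions whose (delta m, delta h)
#' pairs across the MEF -> 2-cell transition are drawn with Pearson
#' correlation `coupling_rho`; hypermethylated maternal gICRs (m = 0.85
#' through the 4-8-cell stage, dropping to 0.45 at blastocyst, 5hmC held
#' at the stage baseline); and a multiplicative chrX 5hmC deficit in XX
#' samples (`x_h_scale`).
#'
#' @param genome A [genome_layout()].
#' @param cpg_spacing Mean bp between CpGs (geometric gaps).
#' @param coverage Mean reads per CpG per assay (Poisson).
#' @param stage_profile data.frame `stage`, `m`, `h` of global means.
#' @param groups,sexes,alleles,replicates Sample design to emit.
#'   `alleles` may include `"combined"` (simulated directly at the
#'   allele-averaged truth).
#' @param block_bp Width of heterogeneity blocks.
#' @param block_sd_m_shared,block_sd_m_stage Additive SDs of the shared
#'   and stage-specific 5mC block effects.
#' @param block_sdlog_h_shared,block_sdlog_h_stage Log-scale SDs of the
#'   multiplicative 5hmC block effects.
#' @param planted_regions data.frame `chrom`, `start`, `end`,
#'   `group_a`, `group_b`, `d_m`, `d_h`, `label`: inside each interval
#'   group_a truth is shifted by `+d/2` and group_b by `-d/2`, so the
#'   a-minus-b difference is the planted delta. `NULL` = default plant
#'   set (see above); use `data.frame()` for none.
#' @param n_coupling,coupling_rho,coupling_sd_m,coupling_sd_h Number of
#'   coupling regions, their target Pearson correlation between delta-m
#'   and delta-h across MEF -> 2-cell, and the SDs of the planted
#'   deltas (means: delta m -0.2, delta h +0.04).
#' @param n_gicr Number of maternal germline imprinting control regions.
#' @param gicr_m_early,gicr_m_blast,x_h_scale gICR maternal-allele 5mC
#'   before/at blastocyst, and the XX chrX 5hmC multiplier.
#' @param allele_mode `"symmetric"` (SCNT-like: parental alleles share
#'   truth) or `"paternal_biased"` (WT-like: paternal 5hmC doubled at
#'   embryonic stages).
#' @param conversion_error Optional false non-conversion rate epsilon
#'   (a read reports unconverted with probability
#'   `p + (1 - p) * epsilon`).
#' @param seed Master integer seed; per-sample substreams are derived
#'   by stable hashing of the sample id.
#' @return A `truth_config` list.
#' @export
truth_config <- function(genome = NULL,
                         cpg_spacing = 100,
                         coverage = 30,
                         stage_profile = .default_stage_profile(),
                         groups = c("MEF", "SCNT_2C", "SCNT_48C",
                                    "SCNT_blast", "WT_2C", "OE_2C"),
                         sexes = c("XX", "XY"),
                         alleles = c("maternal", "paternal"),
                         replicates = 2L,
                         block_bp = 1000,
                         block_sd_m_shared = 0.04,
                         block_sd_m_stage = 0.04,
                         block_sdlog_h_shared = 0.4,
                         block_sdlog_h_stage = 0.3,
                         planted_regions = NULL,
                         n_coupling = 300,
                         coupling_rho = -0.7,
                         coupling_sd_m = 0.12,
                         coupling_sd_h = 0.02,
                         n_gicr = 17,
                         gicr_m_early = 0.85,
                         gicr_m_blast = 0.45,
                         x_h_scale = 0.5,
                         allele_mode = c("symmetric", "paternal_biased"),
                         conversion_error = 0,
                         seed = 17L) {
  if (is.null(genome))
    genome <- genome_layout(c("chr1", "chr2", "chr3", "chr4", "chrX"),
                            rep(2e6, 5), "chrX")
  allele_mode <- match.arg(allele_mode)
  if (!is.finite(cpg_spacing) || cpg_spacing <= 0)
    stop("cpg_spacing must be > 0")
  if (!is.finite(coverage) || coverage <= 0)
    stop("coverage must be > 0")
  stopifnot(all(c("stage", "m", "h") %in% names(stage_profile)))
  if (any(stage_profile$m < 0 | stage_profile$m > 1 |
          stage_profile$h < 0 | stage_profile$h > 1 |
          stage_profile$m + stage_profile$h > 1))
    stop("stage profile levels must lie in [0,1] with m + h <= 1")
  .group_stage(groups)  # validates group names
  if (is.null(planted_regions)) {
    dmr <- .grid_regions(genome, 20, offset = 3e5, step = 3e5, width = 5000)
    dmr$group_a <- "SCNT_2C"; dmr$group_b <- "WT_2C"
    dmr$d_m <- 0.5; dmr$d_h <- 0; dmr$label <- "dmr_recovery"
    dh <- .grid_regions(genome, 8, offset = 20000, step = 4e5, width = 2000)
    dh$group_a <- "SCNT_2C"; dh$group_b <- "MEF"
    dh$d_m <- 0; dh$d_h <- 0.10; dh$label <- "dhmr_gain"
    oe <- .grid_regions(genome, 16, offset = 16000, step = 4e5, width = 2500)
    oe$group_a <- "OE_2C"; oe$group_b <- "SCNT_2C"
    oe$d_m <- -0.35; oe$d_h <- 0.15; oe$label <- "oe_ectopic"
    planted_regions <- rbind(dmr, dh, oe)
  }
  if (nrow(planted_regions))
    .check_intervals(planted_regions, genome, what = "planted regions")
  cfg <- list(genome = genome, cpg_spacing = cpg_spacing,
              coverage = coverage, stage_profile = stage_profile,
              groups = groups, sexes = sexes, alleles = alleles,
              replicates = as.integer(replicates), block_bp = block_bp,
              block_sd_m_shared = block_sd_m_shared,
              block_sd_m_stage = block_sd_m_stage,
              block_sdlog_h_shared = block_sdlog_h_shared,
              block_sdlog_h_stage = block_sdlog_h_stage,
              planted_regions = planted_regions,
              n_coupling = n_coupling, coupling_rho = coupling_rho,
              coupling_sd_m = coupling_sd_m, coupling_sd_h = coupling_sd_h,
              n_gicr = n_gicr, gicr_m_early = gicr_m_early,
              gicr_m_blast = gicr_m_blast, x_h_scale = x_h_scale,
              allele_mode = allele_mode,
              conversion_error = conversion_error,
              seed = as.integer(seed))
  structure(cfg, class = "truth_config")
}

#' Simulate the genome scaffold: CpG positions and annotations
#'
#' CpG positions are drawn with geometric inter-CpG gaps (mean
#' `cpg_spacing`); annotations comprise TSSs (with strand), promoters
#' derived from them, enhancers, maternal gICRs, the planted-region
#' manifest, coupling regions and 100-kb tiles. Deterministic given the
#' config seed.
#'
#' @param cfg A [truth_config()].
#' @return list with `genome`, `cpg` (data.frame `chrom`, `pos`) and
#'   `annotations` (named list of interval data.frames).
#' @export
simulate_genome <- function(cfg) {
  genome <- cfg$genome
  cpg <- .with_seed(.substream_seed(cfg$seed, "cpg"), {
    do.call(rbind, lapply(genome$chrom_names, function(cn) {
      sz <- genome$chrom_sizes[[cn]]
      n_guess <- ceiling(sz / cfg$cpg_spacing * 1.3) + 50
      gaps <- stats::rgeom(n_guess, 1 / cfg$cpg_spacing) + 1
      pos <- cumsum(gaps)
      while (pos[length(pos)] < sz) {
        gaps <- stats::rgeom(n_guess, 1 / cfg$cpg_spacing) + 1
        pos <- c(pos, pos[length(pos)] + cumsum(gaps))
      }
      data.frame(chrom = cn, pos = pos[pos < sz - 1])
    }))
  })
  ann <- .with_seed(.substream_seed(cfg$seed, "annotations"), {
    tss <- do.call(rbind, lapply(genome$chrom_names, function(cn) {
      sz <- genome$chrom_sizes[[cn]]
      n_genes <- max(4, round(sz / 4e4))
      pos <- sort(sample.int(sz - 4000, n_genes) + 2000)
      data.frame(chrom = cn, pos = pos,
                 strand = sample(c("+", "-"), n_genes, replace = TRUE),
                 gene_id = paste0(cn, "_g", seq_len(n_genes)))
    }))
    enh <- do.call(rbind, lapply(genome$chrom_names, function(cn) {
      sz <- genome$chrom_sizes[[cn]]
      n_enh <- max(4, round(sz / 5e4))
      center <- sort(sample.int(sz - 2000, n_enh) + 1000)
      data.frame(chrom = cn, start = center - 500, end = center + 500,
                 enhancer_id = paste0(cn, "_e", seq_len(n_enh)))
    }))
    list(tss = tss, enhancers = enh)
  })
  gicr <- .grid_regions(genome, cfg$n_gicr, offset = 12000, step = 4e5,
                        width = 2000)
  gicr$gicr_id <- sprintf("gICR_%d", seq_len(nrow(gicr)))
  coupling <- .grid_regions(genome, cfg$n_coupling, offset = 30000,
                            step = 25000, width = 2000)
  coupling$region_id <- sprintf("coupling_%d", seq_len(nrow(coupling)))
  annotations <- list(
    tss = ann$tss,
    promoters = make_promoters(ann$tss, genome),
    enhancers = ann$enhancers,
    gicr = gicr,
    planted = cfg$planted_regions,
    coupling = coupling,
    tiles_100kb = tile_genome(genome, 1e5))
  list(genome = genome, cpg = cpg, annotations = annotations)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

## per-(stage, site) baseline truth with block heterogeneity and the
## MEF -> 2-cell coupling overrides; returns list(stage -> df(m, h))
## aligned with sim$cpg rows
.stage_truth <- function(cfg, sim) {
  cpg <- sim$cpg
  stages <- unique(.group_stage(cfg$groups))
  if (cfg$n_coupling > 0 && any(stages == "C2"))
    stages <- union(stages, "MEF")
  prof <- cfg$stage_profile
  block <- floor(cpg$pos / cfg$block_bp)
  bkey <- paste(cpg$chrom, block)
  ublocks <- unique(bkey)
  bidx <- match(bkey, ublocks)
  shared <- .with_seed(.substream_seed(cfg$seed, "blocks_shared"), {
    list(A = stats::rnorm(length(ublocks), 0, cfg$block_sd_m_shared),
         G = stats::rnorm(length(ublocks), 0, cfg$block_sdlog_h_shared))
  })
  out <- list()
  for (st in stages) {
    row <- prof[prof$stage == st, ]
    if (!nrow(row)) stop("stage '", st, "' missing from stage_profile")
    eff <- .with_seed(.substream_seed(cfg$seed, paste0("blocks_", st)), {
      list(a = stats::rnorm(length(ublocks), 0, cfg$block_sd_m_stage),
           g = stats::rnorm(length(ublocks), 0, cfg$block_sdlog_h_stage))
    })
    m <- .clamp01(row$m + shared$A[bidx] + eff$a[bidx])
    h <- .clamp01(row$h * exp(shared$G[bidx] + eff$g[bidx]))
    h <- pmin(h, 1 - m)
    out[[st]] <- data.frame(m = m, h = h)
  }
  coupling <- sim$annotations$coupling
  if (!is.null(coupling) && nrow(coupling) && "C2" %in% stages) {
    deltas <- .with_seed(.substream_seed(cfg$seed, "coupling"), {
      z1 <- stats::rnorm(nrow(coupling))
      z2 <- stats::rnorm(nrow(coupling))
      rho <- cfg$coupling_rho
      data.frame(
        d_m = -0.2 + cfg$coupling_sd_m * z1,
        d_h = 0.04 + cfg$coupling_sd_h *
          (rho * z1 + sqrt(1 - rho^2) * z2))
    })
    coupling$d_m <- deltas$d_m
    coupling$d_h <- deltas$d_h
    mef <- out[["MEF"]]
    c2 <- out[["C2"]]
    for (i in seq_len(nrow(coupling))) {
      inr <- cpg$chrom == coupling$chrom[i] &
        cpg$pos >= coupling$start[i] & cpg$pos < coupling$end[i]
      if (!any(inr)) next
      m_new <- .clamp01(mef$m[inr] + coupling$d_m[i])
      h_new <- .clamp01(mef$h[inr] + coupling$d_h[i])
      h_new <- pmin(h_new, 1 - m_new)
      c2$m[inr] <- m_new
      c2$h[inr] <- h_new
    }
    out[["C2"]] <- c2
    attr(out, "coupling") <- coupling
  }
  out
}

## apply planted group deltas, gICR overrides, allele bias and the
## female-X 5hmC deficit to a stage baseline
.condition_truth <- function(cfg, sim, stage_truth, group, sex, allele) {
  cpg <- sim$cpg
  st <- .group_stage(group)
  tr <- stage_truth[[st]]
  m <- tr$m; h <- tr$h
  pl <- cfg$planted_regions
  if (!is.null(pl) && nrow(pl)) {
    for (i in seq_len(nrow(pl))) {
      sgn <- if (pl$group_a[i] == group) 0.5
             else if (pl$group_b[i] == group) -0.5 else NA
      if (is.na(sgn)) next
      inr <- cpg$chrom == pl$chrom[i] &
        cpg$pos >= pl$start[i] & cpg$pos < pl$end[i]
      if (!any(inr)) next
      m[inr] <- .clamp01(m[inr] + sgn * pl$d_m[i])
      h[inr] <- .clamp01(h[inr] + sgn * pl$d_h[i])
      h[inr] <- pmin(h[inr], 1 - m[inr])
    }
  }
  if (allele %in% c("maternal") && nrow(sim$annotations$gicr)) {
    g_m <- if (st == "blast") cfg$gicr_m_blast else cfg$gicr_m_early
    base_h <- cfg$stage_profile$h[cfg$stage_profile$stage == st]
    gicr <- sim$annotations$gicr
    for (i in seq_len(nrow(gicr))) {
      inr <- cpg$chrom == gicr$chrom[i] &
        cpg$pos >= gicr$start[i] & cpg$pos < gicr$end[i]
      if (!any(inr)) next
      m[inr] <- g_m
      h[inr] <- min(base_h, 1 - g_m)
    }
  }
  if (cfg$allele_mode == "paternal_biased" && allele == "paternal" &&
      group != "MEF")
    h <- pmin(2 * h, 1 - m)
  if (sex == "XX") {
    onx <- cpg$chrom == cfg$genome$x_chrom
    h[onx] <- h[onx] * cfg$x_h_scale
  }
  data.frame(m = m, h = h)
}

#' Simulate BS/ACE count tracks from a truth configuration
#'
#' Draws, for every (group, sex, allele, replicate) in the design and
#' both assays, per-CpG coverage `n ~ Poisson(coverage)` and
#' non-converted counts `k_BS ~ Binomial(n, m + h)`,
#' `k_ACE ~ Binomial(n, h)` (with optional conversion error). The
#' `"combined"` allele is simulated at the maternal/paternal-averaged
#' truth. Per-sample RNG substreams are derived by stable hashing of the
#' sample id, so any subset of the design reproduces identically.
#'
#' @param cfg A [truth_config()].
#' @param sim Output of [simulate_genome()] (regenerated if `NULL`).
#' @return list with `genome`, `cpg`, `annotations`, `truth` (named list
#'   `group|sex|allele` -> data.frame `m`, `h` aligned with `cpg`),
#'   `coupling` (coupling regions with their planted deltas), `samples`
#'   (design table) and `tracks` (named list of count
#'   [methylome_track()]s, two per sample: `<sample_id>|BS` and
#'   `<sample_id>|ACE`).
#' @export
simulate_counts <- function(cfg, sim = NULL) {
  if (is.null(sim)) sim <- simulate_genome(cfg)
  stage_truth <- .stage_truth(cfg, sim)
  cpg <- sim$cpg
  design <- expand.grid(group = cfg$groups, sex = cfg$sexes,
                        allele = cfg$alleles,
                        replicate = seq_len(cfg$replicates),
                        stringsAsFactors = FALSE)
  truth <- list()
  get_truth <- function(group, sex, allele) {
    key <- paste(group, sex, allele, sep = "|")
    if (is.null(truth[[key]])) {
      tr <- if (allele == "combined") {
        tm <- .condition_truth(cfg, sim, stage_truth, group, sex, "maternal")
        tp <- .condition_truth(cfg, sim, stage_truth, group, sex, "paternal")
        data.frame(m = (tm$m + tp$m) / 2, h = (tm$h + tp$h) / 2)
      } else {
        .condition_truth(cfg, sim, stage_truth, group, sex, allele)
      }
      truth[[key]] <<- tr
    }
    truth[[key]]
  }
  eps <- cfg$conversion_error
  tracks <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    tr <- get_truth(d$group, d$sex, d$allele)
    sid <- paste(d$group, d$sex, paste0("rep", d$replicate), d$allele,
                 sep = "_")
    meta <- sample_meta(sid, d$group, d$sex, d$allele, d$replicate)
    for (assay in c("BS", "ACE")) {
      p <- if (assay == "BS") tr$m + tr$h else tr$h
      if (eps > 0) p <- p + (1 - p) * eps
      dat <- .with_seed(.substream_seed(cfg$seed, paste(sid, assay)), {
        n <- stats::rpois(nrow(cpg), cfg$coverage)
        k <- stats::rbinom(nrow(cpg), n, p)
        data.frame(chrom = cpg$chrom, pos = cpg$pos, n = n, k = k)
      })
      tracks[[paste(sid, assay, sep = "|")]] <-
        methylome_track(dat, meta, assay)
    }
  }
  design$sample_id <- paste(design$group, design$sex,
                            paste0("rep", design$replicate),
                            design$allele, sep = "_")
  list(genome = sim$genome, cpg = cpg, annotations = sim$annotations,
       truth = truth, coupling = attr(stage_truth, "coupling"),
       samples = design, tracks = tracks)
}

#' One-call generator: genome scaffold plus count tracks
#'
#' @param cfg A [truth_config()].
#' @return See [simulate_counts()].
#' @export
simulate_methylomes <- function(cfg) simulate_counts(cfg)

#' Select simulated tracks by metadata
#'
#' @param sim Output of [simulate_counts()].
#' @param group,sex,allele,assay Optional filters (`NULL` = any).
#' @return Named list of matching tracks.
#' @export
get_tracks <- function(sim, group = NULL, sex = NULL, allele = NULL,
                       assay = NULL) {
  keep <- vapply(sim$tracks, function(tr) {
    m <- attr(tr, "meta")
    (is.null(group) || m$group %in% group) &&
      (is.null(sex) || m$sex %in% sex) &&
      (is.null(allele) || m$allele %in% allele) &&
      (is.null(assay) || attr(tr, "assay") %in% assay)
  }, logical(1))
  sim$tracks[keep]
}

#' Write a simulated fixture to disk / load it back
#'
#' Writes chrom.sizes, every count track (tsv_kn dialect), all
#' annotation BEDs, the ground-truth level table and a manifest of
#' planted regions; everything round-trips through the package readers.
#'
#' @param sim Output of [simulate_counts()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir` ([write_fixture()]); a `sim`-like list
#'   ([read_fixture()], without truth tables).
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_chrom_sizes(sim$genome, file.path(out_dir, "chrom.sizes"))
  write_bed(sim$cpg |> transform(start = pos, end = pos + 1) |>
              subset(select = c(chrom, start, end)),
            file.path(out_dir, "cpg_sites.bed"))
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(ann_dir, showWarnings = FALSE)
  for (nm in names(sim$annotations)) {
    df <- sim$annotations[[nm]]
    if (nm == "tss") {
      write_bed(transform(df, start = pos, end = pos + 1)[,
                c("chrom", "start", "end", "gene_id", "strand")],
                file.path(ann_dir, "tss.bed"))
    } else if (nrow(df)) {
      write_bed(df, file.path(ann_dir, paste0(nm, ".bed")))
    }
  }
  trk_dir <- file.path(out_dir, "tracks")
  dir.create(trk_dir, showWarnings = FALSE)
  for (nm in names(sim$tracks))
    write_counts(sim$tracks[[nm]],
                 file.path(trk_dir, paste0(gsub("\\|", ".", nm), ".tsv")))
  truth_long <- do.call(rbind, lapply(names(sim$truth), function(key) {
    data.frame(condition = key, chrom = sim$cpg$chrom, pos = sim$cpg$pos,
               m = sim$truth[[key]]$m, h = sim$truth[[key]]$h)
  }))
  utils::write.table(truth_long, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @rdname write_fixture
#' @param dir Fixture directory written by [write_fixture()].
#' @export
read_fixture <- function(dir) {
  genome <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  cpg <- read_bed(file.path(dir, "cpg_sites.bed"))
  cpg <- data.frame(chrom = cpg$chrom, pos = cpg$start)
  files <- list.files(file.path(dir, "tracks"), full.names = TRUE)
  tracks <- list()
  for (f in files) {
    base <- sub("\\.tsv$", "", basename(f))
    assay <- sub(".*\\.", "", base)
    sid <- sub("\\.[^.]+$", "", base)
    parts <- strsplit(sid, "_")[[1]]
    np <- length(parts)
    meta <- sample_meta(
      sid, group = paste(parts[seq_len(np - 3)], collapse = "_"),
      sex = parts[np - 2],
      allele = parts[np],
      replicate = as.integer(sub("rep", "", parts[np - 1])))
    tracks[[paste(sid, assay, sep = "|")]] <-
      read_counts(f, "tsv_kn", meta = meta, assay = assay)
  }
  ann_dir <- file.path(dir, "annotations")
  annotations <- list()
  for (f in list.files(ann_dir, full.names = TRUE)) {
    nm <- sub("\\.bed$", "", basename(f))
    extra <- switch(nm,
                    tss = c("gene_id", "strand"),
                    enhancers = "enhancer_id",
                    gicr = "gicr_id",
                    coupling = c("region_id", "d_m", "d_h"),
                    planted = c("group_a", "group_b", "d_m", "d_h", "label"),
                    character())
    df <- read_bed(f, extra_cols = extra)
    if (nm == "tss") df <- data.frame(chrom = df$chrom, pos = df$start,
                                      strand = df$strand,
                                      gene_id = df$gene_id)
    annotations[[nm]] <- df
  }
  list(genome = genome, cpg = cpg, annotations = annotations,
       tracks = tracks)
}

#' Build an engineered fixture for the reactivation screen
#'
#' Constructs a synthetic gene table plus region sets in which
#' `n_pass` genes satisfy every screen criterion (silent in control,
#' strongly activated, promoter overlapping both an ectopic 5hmC-gain
#' DhMR and a hypo DMR) and `n_fail` genes each violate exactly one
#' criterion (high control expression; insufficient fold change;
#' non-significant p; promoter gain-DhMR missing or merely "enhanced",
#' i.e. control 5hmC already high; hypo DMR missing), cycling through
#' the five failure modes.
#'
#' @param seed Integer seed for jittered magnitudes.
#' @param n_pass,n_fail Number of passing / failing genes.
#' @param params [screen_params()] whose thresholds the fixture brackets.
#' @return list with `deg` (DEG table), `gain_dhmrs` (with `control_h`),
#'   `hypo_dmrs`, `promoters`, `tss` and `truth` (per-gene expected
#'   outcome and failure mode).
#' @export
simulate_screen_fixture <- function(seed = 1, n_pass = 10, n_fail = 30,
                                    params = screen_params()) {
  n <- n_pass + n_fail
  genes <- sprintf("gene%03d", seq_len(n))
  modes <- c(rep("pass", n_pass),
             rep_len(c("expressed_in_control", "low_lfc", "high_p",
                       "no_ectopic_dhmr", "no_hypo_dmr"), n_fail))
  .with_seed(seed, {
    tss_pos <- 5000 + (seq_len(n) - 1) * 20000
    tss <- data.frame(chrom = "chr1", pos = tss_pos, strand = "+",
                      gene_id = genes)
    gl <- genome_layout("chr1", max(tss_pos) + 10000, "chr1")
    promoters <- make_promoters(tss, gl)
    expr_ctrl <- ifelse(modes == "expressed_in_control",
                        params$silent_max_expr * 4 +
                          stats::runif(n, 0, 10),
                        stats::runif(n, 0, params$silent_max_expr * 0.6))
    lfc <- ifelse(modes == "low_lfc",
                  stats::runif(n, 0.1, params$deg_lfc * 0.8),
                  stats::runif(n, params$deg_lfc + 0.5, params$deg_lfc + 3))
    pval <- ifelse(modes == "high_p",
                   stats::runif(n, 0.2, 0.9),
                   stats::runif(n, 1e-6, params$deg_p * 0.5))
    deg <- data.frame(gene_id = genes, log2fc = lfc, p = pval,
                      mean_expr_control = expr_ctrl,
                      mean_expr_treatment = expr_ctrl * 2^lfc + 1)
    ## a gain DhMR and a hypo DMR inside each promoter, except where a
    ## failure mode removes or disqualifies one
    mk <- function(off, width) data.frame(
      chrom = "chr1", start = promoters$start + off,
      end = promoters$start + off + width, gene_id = genes)
    gains <- mk(100, 300)
    gains$control_h <- ifelse(modes == "no_ectopic_dhmr",
                              params$ectopic_h_max * 3,
                              params$ectopic_h_max * 0.2)
    hypo <- mk(600, 300)
    hypo <- hypo[modes != "no_hypo_dmr", , drop = FALSE]
    list(deg = deg, gain_dhmrs = gains, hypo_dmrs = hypo,
         promoters = promoters, tss = tss,
         truth = data.frame(gene_id = genes, mode = modes,
                            should_pass = modes == "pass"))
  })
}
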