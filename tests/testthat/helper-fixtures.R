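# Shared simulated fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# flat-truth config: constant (m, h) everywhere, no plants or jitter
flat_config <- function(m = 0.5, h = 0.1, coverage = 30, seed = 11,
                        chrom_bp = 1.01e6, spacing = 100,
                        groups = "MEF", sexes = "XY",
                        alleles = "combined", replicates = 1L) {
  truth_config(
    genome = genome_layout(c("chr1", "chrX"), c(chrom_bp, 5e4), "chrX"),
    cpg_spacing = spacing, coverage = coverage,
    stage_profile = data.frame(stage = c("MEF", "C2", "C48", "blast"),
                               m = m, h = h),
    groups = groups, sexes = sexes, alleles = alleles,
    replicates = replicates,
    block_sd_m_shared = 0, block_sd_m_stage = 0,
    block_sdlog_h_shared = 0, block_sdlog_h_stage = 0,
    planted_regions = data.frame(), n_coupling = 0, n_gicr = 0,
    seed = seed)
}

# small stage-structured world used by caller/dynamics unit tests
small_world <- function() cached("small_world", function() {
  pl <- data.frame(
    chrom = rep(c("chr1", "chr2"), each = 3),
    start = rep(c(2e5, 5e5, 8e5), 2),
    end = rep(c(2e5, 5e5, 8e5), 2) + 5000,
    group_a = "SCNT_2C", group_b = "WT_2C",
    d_m = 0.5, d_h = 0, label = "dmr_recovery")
  cfg <- truth_config(
    genome = genome_layout(c("chr1", "chr2", "chrX"),
                           c(1e6, 1e6, 5e5), "chrX"),
    groups = c("MEF", "SCNT_2C", "WT_2C"), sexes = "XX",
    alleles = "combined", planted_regions = pl,
    n_coupling = 30, n_gicr = 4, seed = 7)
  list(cfg = cfg, sim = simulate_counts(cfg))
})

# toy paired-site table for oracle comparisons: two groups of levels
# over a <= 50 kb genome
toy_sites <- function(seed = 3, n = 300, chrom_bp = 30000,
                      shift_at = NULL, shift = 0.4) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_bp - 2, n))
  la <- pmin(pmax(stats::rnorm(n, 0.6, 0.08), 0), 1)
  lb <- la + stats::rnorm(n, 0, 0.05)
  if (!is.null(shift_at))
    lb[pos >= shift_at[1] & pos < shift_at[2]] <-
      la[pos >= shift_at[1] & pos < shift_at[2]] - shift
  data.frame(chrom = "chr1", pos = pos, la = la,
             lb = pmin(pmax(lb, 0), 1))
}

toy_genome <- function(chrom_bp = 30000)
  genome_layout(c("chr1", "chrX"), c(chrom_bp, 1000), "chrX")
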