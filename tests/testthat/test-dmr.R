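test_that("tiling keeps CpG-dense tiles only", {
  g <- toy_genome(250)
  sites <- data.frame(chrom = "chr1", pos = c(10, 50, 120))
  tiles <- tile_and_filter(g, sites, 100, 2)
  expect_equal(tiles$start, 0)
  expect_equal(tiles$end, 100)
  expect_equal(nrow(tile_and_filter(g, sites[0, ], 100, 2)), 0)
  # truncation at the chromosome end
  sites2 <- data.frame(chrom = "chr1", pos = c(210, 240))
  expect_equal(tile_and_filter(g, sites2, 100, 2)$end, 250)
})

test_that("window scoring matches an independent t-test and handles degeneracy", {
  g <- toy_genome(1200)
  set.seed(1)
  pos <- sort(sample(0:999, 10))
  la <- 0.9 + rnorm(10, 0, 0.01)
  lb <- 0.1 + rnorm(10, 0, 0.01)
  sites <- data.frame(chrom = "chr1", pos = pos,
                      la = pmin(la, 1), lb = pmax(lb, 0))
  params <- caller_params("methylation")
  tiles <- tile_and_filter(g, sites, 100, 1)
  win <- sliding_window_test(sites, tiles, g, params)
  w0 <- win[win$start == 0, ]
  expect_equal(w0$diff, mean(sites$la) - mean(sites$lb), tolerance = 1e-12)
  expect_lt(w0$p, 1e-6)
  expect_equal(w0$p, oracle_t_p(sites$la, sites$lb), tolerance = 1e-12)

  # identical levels in both groups -> defined degenerate p = 1
  sites$lb <- sites$la
  win <- sliding_window_test(sites, tiles, g, params)
  expect_true(all(win$p == 1))

  # empty input -> empty output
  expect_equal(nrow(sliding_window_test(sites[0, ], tiles, g, params)), 0)
})

test_that("significant-window merging unions overlapping extents only", {
  sites <- data.frame(chrom = "chr1",
                      pos = c(100, 200, 500, 900, 1100, 2100, 2500),
                      la = c(0.9, 0.8, 0.85, 0.9, 0.8, 0.9, 0.85),
                      lb = c(0.1, 0.2, 0.15, 0.1, 0.2, 0.1, 0.15))
  wins <- data.frame(chrom = "chr1",
                     start = c(0, 300, 2000), end = c(1000, 1300, 3000),
                     p = c(0.05, 0.08, 0.05))
  merged <- merge_significant_windows(wins, sites, merge_p = 0.1)
  expect_equal(merged$start, c(0, 2000))
  expect_equal(merged$end, c(1300, 3000))
  expect_equal(merged$n_cpg, c(5L, 2L))

  wins$p <- c(0.05, 0.5, 0.05)  # middle window not significant
  merged <- merge_significant_windows(wins, sites, merge_p = 0.1)
  expect_equal(merged$start, c(0, 2000))
  expect_equal(merged$end, c(1000, 3000))

  wins$p <- 0.2
  expect_equal(nrow(merge_significant_windows(wins, sites, 0.1)), 0)
})

test_that("classification applies the published thresholds per mode", {
  mk <- function(ma, mb) data.frame(chrom = "chr1", start = 0, end = 10,
                                    mean_a = ma, mean_b = mb,
                                    diff = ma - mb)
  pm <- caller_params("methylation")
  expect_equal(classify_regions(mk(0.9, 0.3), pm)$region_class, "hyper")
  expect_equal(classify_regions(mk(0.3, 0.9), pm)$region_class, "hypo")
  expect_equal(classify_regions(mk(0.8, 0.75), pm)$region_class,
               "stable_high")
  expect_equal(classify_regions(mk(0.5, 0.4), pm)$region_class, "none")
  ph <- caller_params("hydroxymethylation")
  expect_equal(classify_regions(mk(0.10, 0.05), ph)$region_class, "hyper")
  expect_equal(classify_regions(mk(0.07, 0.06), ph)$region_class,
               "stable_high")
  expect_equal(classify_regions(mk(0.04, 0.02), ph)$region_class,
               "stable_low")
})

test_that("same-class merging bridges gaps up to 10 kb and is idempotent", {
  sites <- data.frame(chrom = "chr1",
                      pos = c(100, 500, 5100, 5500, 20100, 20500),
                      la = 0.9, lb = 0.1)
  mk <- function(starts, classes) data.frame(
    chrom = "chr1", start = starts, end = starts + 1000,
    region_class = classes)
  params <- caller_params("methylation")
  m <- merge_same_class(mk(c(0, 5000), c("hyper", "hyper")), sites, params)
  expect_equal(nrow(m), 1)
  expect_equal(m$end, 6000)
  m <- merge_same_class(mk(c(0, 20000), c("hyper", "hyper")), sites, params)
  expect_equal(nrow(m), 2)
  m <- merge_same_class(mk(c(0, 5000), c("hyper", "hypo")), sites, params)
  expect_equal(nrow(m), 2)
  once <- merge_same_class(mk(c(0, 5000, 20000), rep("hyper", 3)),
                           sites, params)
  expect_equal(merge_same_class(once, sites, params), once)
})

test_that("finalization enforces CpG floors, BH control and stable retention", {
  params <- caller_params("methylation")
  reg <- data.frame(chrom = "chr1", start = c(0, 2000), end = c(1000, 3000),
                    mean_a = c(0.9, 0.9), mean_b = c(0.2, 0.2),
                    diff = 0.7, p = c(0.01, 0.01),
                    n_cpg = c(2L, 5L),
                    region_class = "hyper")
  out <- finalize_regions(reg, params)
  expect_equal(out$start, 2000)  # 2-CpG region dropped regardless of q
  single <- finalize_regions(reg[2, ], params)
  expect_equal(single$q, 0.01)   # BH with one test is the identity
  stable <- data.frame(chrom = "chr1", start = 0, end = 1000,
                       mean_a = 0.8, mean_b = 0.79, diff = 0.01,
                       p = 0.9, n_cpg = 10L, region_class = "stable_high")
  expect_equal(nrow(finalize_regions(stable, params)), 1)
  stable$p <- 0.01  # significant -> not a stable region
  expect_equal(nrow(finalize_regions(stable, params)), 0)
})

test_that("the full caller equals brute-force enumeration on toy genomes", {
  params <- caller_params("methylation")
  for (sc in list(toy_sites(seed = 3, shift_at = c(8000, 12000)),
                  toy_sites(seed = 4),
                  toy_sites(seed = 5, n = 150, chrom_bp = 50000,
                            shift_at = c(20000, 26000), shift = 0.5))) {
    g <- toy_genome(max(sc$pos) + 10)
    mk <- function(level) methylome_track(
      data.frame(chrom = sc$chrom, pos = sc$pos, level = level),
      sample_meta("s"), "level_m")
    got <- call_dmrs(list(mk(sc$la)), list(mk(sc$lb)), g, params)
    want <- oracle_call_dmrs(sc, g, params)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$region_class, want$region_class)
    expect_equal(got$n_cpg, want$n_cpg)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$q, want$q, tolerance = 1e-12)
  }
})

test_that("caller output is antisymmetric and null on identical groups", {
  w <- small_world()
  sim <- w$sim
  pa <- get_tracks(sim, group = "SCNT_2C", assay = "BS")
  pb <- get_tracks(sim, group = "WT_2C", assay = "BS")
  params <- caller_params("methylation")
  fwd <- call_dmrs(pa, pb, sim$genome, params)
  rev <- call_dmrs(pb, pa, sim$genome, params)
  expect_equal(fwd$start[fwd$region_class == "hyper"],
               rev$start[rev$region_class == "hypo"])
  expect_equal(fwd$diff[fwd$region_class == "hyper"],
               -rev$diff[rev$region_class == "hypo"], tolerance = 1e-12)
  same <- call_dmrs(pa, pa, sim$genome, params)
  expect_equal(sum(same$region_class %in% c("hyper", "hypo")), 0)
  # emitted regions never overlap within a class
  for (cls in unique(fwd$region_class)) {
    s <- fwd[fwd$region_class == cls, ]
    s <- s[order(s$chrom, s$start), ]
    by_chrom <- split(s, s$chrom)
    for (b in by_chrom)
      if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
})

test_that("planted differential regions are recovered on the small world", {
  w <- small_world()
  sim <- w$sim
  dmrs <- call_dmrs(get_tracks(sim, group = "SCNT_2C", assay = "BS"),
                    get_tracks(sim, group = "WT_2C", assay = "BS"),
                    sim$genome, caller_params("methylation"))
  hyper <- dmrs[dmrs$region_class == "hyper", ]
  planted <- w$cfg$planted_regions
  expect_gte(recovered_fraction(planted, hyper), 5 / 6)
})
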