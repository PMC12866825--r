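## build replicate 5hmC level tracks with a planted region of different
## level, used by the stage-dynamics tests
.h_tracks <- function(base, region_level = NULL, region = c(5000, 10000),
                      n = 400, chrom_bp = 40000, seed = 1, reps = 2,
                      group = "MEF") {
  set.seed(99)  # same CpG positions for every stage/group
  pos <- sort(sample.int(chrom_bp - 10, n))
  set.seed(seed)
  lapply(seq_len(reps), function(r) {
    lv <- pmin(pmax(base + rnorm(n, 0, 0.004), 0), 1)
    if (!is.null(region_level)) {
      inr <- pos >= region[1] & pos < region[2]
      lv[inr] <- pmin(pmax(region_level + rnorm(sum(inr), 0, 0.004), 0), 1)
    }
    methylome_track(data.frame(chrom = "chr1", pos = pos, level = lv),
                    sample_meta(paste0(group, "_r", r), group = group,
                                replicate = r), "level_h")
  })
}

test_that("stage dynamics split regions into gain/loss/stable categories", {
  g <- toy_genome(40000)
  s1 <- .h_tracks(0.02, region_level = 0.02, seed = 1)
  s2 <- .h_tracks(0.02, region_level = 0.12, seed = 2, group = "SCNT_2C")
  dyn <- categorize_dynamics(s1, s2, g)
  expect_gte(nrow(dyn$gain), 1)
  expect_true(any(dyn$gain$start < 10000 & dyn$gain$end > 5000))
  expect_equal(nrow(dyn$loss), 0)
  # background h = 0.02 is stable low; planted region is the only gain
  expect_true(all(dyn$stable_low$diff < 0.03))
  # swapping the stage order swaps gain and loss exactly
  rev <- categorize_dynamics(s2, s1, g)
  expect_equal(dyn$gain$start, rev$loss$start)
  expect_equal(dyn$gain$end, rev$loss$end)
  # disjoint categories
  all_regions <- do.call(rbind, dyn)
  if (nrow(all_regions) > 1) {
    o <- order(all_regions$chrom, all_regions$start)
    s <- all_regions[o, ]
    for (cn in unique(s$chrom)) {
      b <- s[s$chrom == cn, ]
      if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
  }
  # stable-high at persistent h > 0.05
  hi1 <- .h_tracks(0.08, seed = 3)
  hi2 <- .h_tracks(0.08, seed = 4, group = "SCNT_2C")
  dyn_hi <- categorize_dynamics(hi1, hi2, g)
  expect_gte(nrow(dyn_hi$stable_high), 1)
  expect_equal(nrow(dyn_hi$gain) + nrow(dyn_hi$loss), 0)
  # mismatched genomes are refused
  bad <- .h_tracks(0.02)
  bad <- lapply(bad, function(t) { t$chrom <- "chr9"; t })
  expect_error(categorize_dynamics(bad, s2, g), "genome")
})

test_that("region deltas and their correlation behave analytically", {
  # d_h = -d_m exactly -> r = -1
  set.seed(9)
  d <- data.frame(d_m = rnorm(100), d_h = NA)
  d$d_h <- -d$d_m
  expect_equal(delta_correlation(d)$r, -1, tolerance = 1e-12)
  # independent deltas -> |r| small at n = 1000
  d <- data.frame(d_m = rnorm(1000), d_h = rnorm(1000))
  expect_lt(abs(delta_correlation(d)$r), 0.1)
  expect_error(delta_correlation(d[1:2, ]), "at least 3")

  # region_deltas equals a direct weighted-mean computation
  pos <- c(10, 20, 30, 110, 120)
  mk <- function(lv, w) methylome_track(
    data.frame(chrom = "chr1", pos = pos, level = lv, weight = w),
    sample_meta("s"), "level_m")
  regions <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200))
  m1 <- list(mk(c(.1, .2, .3, .5, .7), c(1, 2, 1, 1, 3)))
  m2 <- list(mk(c(.4, .1, .6, .2, .2), c(2, 1, 1, 2, 2)))
  dd <- region_deltas(regions, m1, m1, m2, m2)
  w1 <- c(1, 2, 1); w2 <- c(2, 1, 1)
  exp_d1 <- sum(c(.4, .1, .6) * w2) / sum(w2) -
    sum(c(.1, .2, .3) * w1) / sum(w1)
  expect_equal(dd$d_m[1], exp_d1, tolerance = 1e-12)
  expect_equal(dd$d_m, dd$d_h)  # same tracks supplied for both states
})

test_that("chromosome summaries detect a planted X 5hmC deficit", {
  g <- genome_layout(c("chr1", "chr2", "chrX"), c(4e5, 4e5, 4e5), "chrX")
  set.seed(5)
  pos <- sort(sample.int(4e5 - 10, 4000))
  mk_level <- function(chrom, scale) {
    lv <- pmin(pmax(0.06 * scale + rnorm(length(pos), 0, 0.01), 0), 1)
    data.frame(chrom = chrom, pos = pos, level = lv)
  }
  tr <- methylome_track(rbind(mk_level("chr1", 1), mk_level("chr2", 1),
                              mk_level("chrX", 0.5)),
                        sample_meta("s"), "level_h")
  tiles <- tile_genome(g, 1e5)
  cs <- chromosome_summary(tr, tiles, "chrX")
  expect_lt(cs$x_median, cs$autosome_median)
  expect_lt(cs$p_x_vs_autosome, 0.01)
  expect_equal(nrow(cs$per_chrom), 3)
  # no covered X tiles -> error
  tr_aut <- methylome_track(rbind(mk_level("chr1", 1), mk_level("chr2", 1)),
                            sample_meta("s"), "level_h")
  expect_error(chromosome_summary(tr_aut, tiles, "chrX"), "X chromosome")
})

test_that("gICR panel equals brute-force coverage-weighted means", {
  gicr <- data.frame(chrom = "chr1", start = c(0, 1000, 5000),
                     end = c(100, 1100, 5100),
                     gicr_id = c("g1", "g2", "g3"))
  df <- data.frame(chrom = "chr1", pos = c(10, 50, 1010, 1050),
                   level = c(0.9, 0.7, 0.3, 0.5),
                   weight = c(10, 30, 20, 20))
  tr <- methylome_track(df, sample_meta("s", group = "MEF",
                                        allele = "maternal"), "level_m")
  panel <- gicr_panel(tr, gicr)
  expect_equal(nrow(panel), 2)  # g3 has no covered CpG -> absent row
  expect_equal(panel$mean_level[panel$gicr_id == "g1"],
               (0.9 * 10 + 0.7 * 30) / 40, tolerance = 1e-12)
  expect_equal(panel$mean_level[panel$gicr_id == "g2"], 0.4,
               tolerance = 1e-12)
  expect_equal(panel$allele, c("maternal", "maternal"))
})

test_that("X/A expression ratios follow read-sum semantics", {
  expr <- matrix(1, nrow = 10, ncol = 2,
                 dimnames = list(paste0("g", 1:10), c("s1", "s2")))
  chrom <- setNames(c(rep("chrA", 9), "chrX"), paste0("g", 1:10))
  r <- xa_ratio(expr, chrom, "chrX")
  expect_equal(unname(r), c(1 / 9, 1 / 9), tolerance = 1e-12)
  expr["g10", ] <- 0  # all X genes silenced
  expect_equal(unname(xa_ratio(expr, chrom, "chrX")), c(0, 0))
  expr[1:9, ] <- 0    # no autosomal expression
  expect_error(xa_ratio(expr, chrom, "chrX"), "autosomal")
  expect_error(xa_ratio(expr, chrom[-1], "chrX"), "without chromosome")
})
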