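test_that("genome layout validates names, sizes and the X chromosome", {
  g <- genome_layout(c("chr1", "chrX"), c(100, 200), "chrX")
  expect_equal(unname(g$chrom_sizes["chrX"]), 200)
  expect_equal(autosomes(g), "chr1")
  expect_error(genome_layout(c("a", "a"), c(1, 2), "a"), "unique")
  expect_error(genome_layout("chr1", 0, "chr1"), "> 0")
  expect_error(genome_layout("chr1", 10, "chrX"), "x_chrom")
})

test_that("genome tiling truncates the last tile at the chromosome end", {
  g <- genome_layout(c("chr1", "chrX"), c(250, 100), "chrX")
  tiles <- tile_genome(g, 100)
  c1 <- tiles[tiles$chrom == "chr1", ]
  expect_equal(c1$start, c(0, 100, 200))
  expect_equal(c1$end, c(100, 200, 250))
  expect_equal(nrow(tiles[tiles$chrom == "chrX", ]), 1)
})

test_that("count reading handles both dialects, empty files and bad counts", {
  tmp <- withr::local_tempfile()
  writeLines("chr1\t100\t101\t80\t8\t2", tmp)
  tr <- read_counts(tmp, "bedgraph_pct_counts")
  expect_equal(tr$pos, 100)
  expect_equal(tr$n, 10)
  expect_equal(tr$k, 8)

  writeLines("chr1\t100\t101\t8\t10", tmp)
  tr <- read_counts(tmp, "tsv_kn")
  expect_equal(tr$k, 8)
  expect_equal(tr$n, 10)

  writeLines(character(), tmp)
  expect_equal(nrow(read_counts(tmp, "tsv_kn")), 0)

  writeLines("chr1\t100\t101\t5\t3", tmp)  # k > n
  expect_error(read_counts(tmp, "tsv_kn"), "line 1")
  writeLines(c("chr1\t1\t2\t1\t5", "chr1\tx"), tmp)
  expect_error(read_counts(tmp, "tsv_kn"), "line 2")
})

test_that("count and region tables round-trip through their writers", {
  tmp <- withr::local_tempfile()
  tr <- methylome_track(
    data.frame(chrom = c("chr1", "chr1", "chr2"), pos = c(5, 50, 7),
               n = c(10, 3, 0), k = c(9, 0, 0)),
    sample_meta("s1"), "BS")
  for (dialect in c("tsv_kn", "bedgraph_pct_counts")) {
    write_counts(tr, tmp, dialect)
    back <- read_counts(tmp, dialect, meta = sample_meta("s1"))
    expect_equal(as.data.frame(back), as.data.frame(tr))
  }

  reg <- region_table(chrom = c("chr1", "chr2"), start = c(0, 10),
                      end = c(100, 400),
                      region_class = c("hyper", "stable_low"),
                      mean_a = c(0.8, 0.03), mean_b = c(0.2, 0.04),
                      p = c(1e-5, 0.4), q = c(1e-4, 0.5),
                      n_cpg = c(12L, 4L))
  write_regions(reg, tmp)
  expect_equal(read_regions(reg_path <- tmp), reg, tolerance = 1e-12)
  expect_error(region_table(chrom = "chr1", start = 10, end = 10,
                            region_class = "hyper"),
               "start < end")
})

test_that("CpG dyad collapsing sums the minus-strand G and is idempotent", {
  cpg <- data.frame(chrom = "chr1", pos = c(10, 30))
  raw <- data.frame(chrom = "chr1", pos = c(10, 11, 30, 31),
                    n = c(5, 7, 2, 3), k = c(4, 6, 0, 1))
  once <- collapse_cpg_dyads(raw, cpg)
  expect_equal(once$pos, c(10, 30))
  expect_equal(once$n, c(12, 5))
  expect_equal(once$k, c(10, 1))
  expect_equal(collapse_cpg_dyads(once, cpg), once)
})

test_that("promoters are strand-aware and clipped to chromosome bounds", {
  g <- genome_layout("chr1", 10000, "chr1")
  tss <- data.frame(chrom = "chr1", pos = c(5000, 5000, 300),
                    strand = c("+", "-", "+"),
                    gene_id = c("a", "b", "c"))
  pr <- make_promoters(tss, g)
  pr <- pr[order(pr$gene_id), ]
  expect_equal(pr$start, c(4000, 4500, 0))
  expect_equal(pr$end, c(5500, 6000, 800))
  expect_error(make_promoters(data.frame(chrom = "chr1", pos = 1000), g),
               "strand")
})

test_that("chrom.sizes files round-trip", {
  tmp <- withr::local_tempfile()
  g <- genome_layout(c("chr1", "chr2", "chrX"), c(100, 250, 70), "chrX")
  write_chrom_sizes(g, tmp)
  expect_equal(read_chrom_sizes(tmp), g)
})
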