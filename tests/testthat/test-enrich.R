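test_that("overlap arithmetic is symmetric and overlap-aware", {
  a <- data.frame(chrom = "chr1", start = 0, end = 100)
  b <- data.frame(chrom = "chr1", start = 50, end = 150)
  expect_equal(overlap_bp(a, b), 50)
  expect_equal(overlap_bp(b, a), 50)
  expect_equal(overlap_bp(a, data.frame(chrom = "chr1", start = 500,
                                        end = 600)), 0)
  many <- data.frame(chrom = "chr1", start = c(0, 400, 450),
                     end = c(500, 1000, 1200))  # self-overlapping
  expect_equal(total_bp(many), 1200)
  expect_equal(overlap_bp(many, many), 1200)
})

## lay out intervals so the enrichment table has exactly the cells
## (a, b; c, d): background [0, a+b+c+d), regions [0, a+b),
## element [b, b+a+c)
table_to_sets <- function(a, b, c, d) {
  tot <- a + b + c + d
  list(dmrs = data.frame(chrom = "chr1", start = 0, end = a + b),
       element = if (a + c > 0)
         data.frame(chrom = "chr1", start = b, end = b + a + c)
       else data.frame(chrom = character(), start = numeric(),
                       end = numeric()),
       background = data.frame(chrom = "chr1", start = 0, end = tot))
}

test_that("enrichment builds the published cumulative-length table", {
  s <- table_to_sets(50, 50, 500, 9500)
  res <- enrichment_score(s$dmrs, s$element, s$background)
  expect_equal(c(res$dmr_bp_in, res$dmr_bp_out, res$bg_bp_in,
                 res$bg_bp_out), c(50, 50, 500, 9500))
  expect_equal(res$p, oracle_fisher_two_sided(50, 50, 500, 9500),
               tolerance = 1e-9)
  expect_equal(res$score, -log10(res$p))

  # fully symmetric table -> p = 1, score exactly 0
  s <- table_to_sets(1, 1, 1, 1)
  res <- enrichment_score(s$dmrs, s$element, s$background)
  expect_identical(res$score, 0)

  # regions entirely inside a tiny element -> strong enrichment
  dmrs <- data.frame(chrom = "chr1", start = 100, end = 200)
  element <- data.frame(chrom = "chr1", start = 90, end = 210)
  bg <- data.frame(chrom = "chr1", start = 0, end = 100000)
  res <- enrichment_score(dmrs, element, bg)
  expect_gt(res$score, 10)
  expect_gt(res$odds_ratio, 1)

  expect_error(enrichment_score(dmrs[0, ], element, bg), "empty")
  expect_error(enrichment_score(dmrs, element, bg[0, ]), "empty")
  expect_warning(
    enrichment_score(dmrs, element,
                     data.frame(chrom = "chr1", start = 150, end = 1e5)),
    "cover")
})

test_that("the Fisher path matches hypergeometric enumeration on random tables", {
  set.seed(42)
  for (i in 1:200) {
    tot <- sample(4:2000, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]
    c <- cuts[3] - cuts[2]; d <- tot - cuts[3]
    if (a + b == 0 || c + d == 0) next
    got <- fisher_bp_test(a, b, c, d)$p
    want <- oracle_fisher_two_sided(a, b, c, d)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("enhancers map to the nearest TSS inside 100 kb with a stable tie-break", {
  tss <- data.frame(chrom = "chr1", pos = c(200000, 300000),
                    gene_id = c("gA", "gB"))
  enh <- data.frame(chrom = "chr1",
                    start = c(149500, 249500, 599500),
                    end = c(150500, 250500, 600500))
  res <- assign_enhancers_to_genes(enh, tss)
  expect_equal(res$gene_id[1], "gA")        # 50 kb away -> assigned
  expect_equal(res$tss_dist[1], 50000)
  expect_equal(res$gene_id[2], "gA")        # equidistant -> lower coord
  expect_true(is.na(res$gene_id[3]))        # nearest TSS 300 kb -> none
  at_limit <- assign_enhancers_to_genes(
    data.frame(chrom = "chr1", start = 399500, end = 400500), tss)
  expect_true(is.na(at_limit$gene_id))      # exactly 100 kb: < is strict
})

test_that("enhancer 5hmC classes partition the input", {
  enh <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300) * 10,
                    end = c(0, 100, 200, 300) * 10 + 50)
  gain <- data.frame(chrom = "chr1", start = c(0, 2000), end = c(20, 2020))
  stable <- data.frame(chrom = "chr1", start = c(1000, 2030),
                       end = c(1020, 2050))
  res <- classify_enhancer_5hmc(enh, gain, stable)
  expect_equal(res$enhancer_class, c("NGE", "SHE", "BVE", "other"))
  expect_true(all(res$enhancer_class %in%
                    c("NGE", "SHE", "BVE", "other")))
  expect_equal(length(res$enhancer_class), nrow(enh))
})
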