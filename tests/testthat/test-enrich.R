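# Permutation enrichment: landmark construction, shuffling, overlap
# statistics and the empirical test.

test_that("landmark construction follows the stated flank geometry", {
  chl <- c(chrA = 50e6)
  lm <- build_landmarks(chl, centromeres = c(chrA = 20e6))
  expect_equal(lm$subtelomeric,
               tibble::tibble(chrom = "chrA", start = c(0, 48e6),
                              end = c(2e6, 50e6)))
  expect_equal(lm$pericentromeric,
               tibble::tibble(chrom = "chrA", start = 18e6, end = 22e6))

  # microchromosome with the short flank: 300 kb ends, 400 kb free middle
  chl2 <- c(micro = 1e6)
  lm2 <- build_landmarks(chl2, centromeres = c(micro = 5e5),
                         short_chroms = "micro")
  expect_equal(lm2$subtelomeric$end[1] - lm2$subtelomeric$start[1], 3e5)
  expect_equal(lm2$subtelomeric$start[2], 7e5)
  expect_equal(lm2$pericentromeric,
               tibble::tibble(chrom = "micro", start = 2e5, end = 8e5))

  # a 3 Mb chromosome with 2 Mb flanks is fully covered after merging
  chl3 <- c(chr1 = 3e6)
  lm3 <- build_landmarks(chl3, centromeres = c(chr1 = 1.5e6))
  expect_equal(lm3$subtelomeric, tibble::tibble(chrom = "chr1", start = 0,
                                                end = 3e6))
  expect_equal(lm3$pericentromeric, tibble::tibble(chrom = "chr1", start = 0,
                                                   end = 3e6))

  # chromosomes without a centromere only contribute subtelomeric regions
  expect_warning(
    lm4 <- build_landmarks(c(chr1 = 5e6, chr2 = 5e6),
                           centromeres = c(chr1 = 2e6)),
    "chr2"
  )
  expect_false("chr2" %in% lm4$pericentromeric$chrom)

  expect_error(build_landmarks(chl, flank = -1), class = "sdscape_invalid_spec")
})

test_that("random placement preserves lengths, stays disjoint, reproduces", {
  chl <- c(chr1 = 1e6, chr2 = 5e5)
  regions <- tibble::tibble(chrom = "chr1", start = 0,
                            end = c(1000, 5000, 20000))
  s1 <- shuffle_regions(regions, chl, seed = 3)
  s2 <- shuffle_regions(regions, chl, seed = 3)
  expect_identical(s1, s2)
  expect_setequal(s1$end - s1$start, c(1000, 5000, 20000))
  expect_true(all(s1$start >= 0))
  expect_true(all(s1$end <= chl[s1$chrom]))

  # pairwise disjoint and length-preserving over many replicates
  for (i in 1:50) {
    s <- shuffle_regions(regions, chl, seed = 100 + i)
    expect_equal(sum(s$end - s$start), 26000)
    expect_equal(nrow(merge_intervals(s)), 3)
  }

  # pigeonhole: regions totalling ~100% of the genome cannot be placed
  expect_error(
    shuffle_regions(tibble::tibble(chrom = "chr1", start = 0,
                                   end = rep(499000, 3)), chl, seed = 1),
    class = "sdscape_placement_error"
  )

  # start positions are uniform: chi-square GOF over 10 bins
  starts <- vapply(1:1000, function(i) {
    shuffle_regions(tibble::tibble(chrom = "c", start = 0, end = 10000),
                    c(c = 1e6), seed = 5000 + i)$start
  }, numeric(1))
  ct <- table(cut(starts, breaks = seq(0, 990000, length.out = 11)))
  expect_gt(stats::chisq.test(ct)$p.value, 0.01)
})

test_that("overlap statistics match hand arithmetic and the bitmap oracle", {
  lms <- tibble::tibble(chrom = "chr1", start = c(0, 200), end = c(100, 300))
  rgs <- tibble::tibble(chrom = "chr1", start = 50, end = 250)
  expect_equal(overlap_statistic(rgs, lms, "count"), 2)
  expect_equal(overlap_statistic(rgs, lms, "length"), 100)
  disjoint <- tibble::tibble(chrom = "chr1", start = 500, end = 600)
  expect_equal(overlap_statistic(disjoint, lms, "count"), 0)
  expect_equal(overlap_statistic(disjoint, lms, "length"), 0)

  # randomized 500-interval case equals the per-base bitmap oracle
  chl <- c(chr1 = 2e5, chr2 = 2e5)
  set.seed(61)
  rnd <- function(n, w) {
    ch <- sample(names(chl), n, replace = TRUE)
    st <- floor(runif(n, 0, chl[ch] - w))
    tibble::tibble(chrom = ch, start = st, end = st + w)
  }
  A <- merge_intervals(rnd(500, 300))
  B <- merge_intervals(rnd(500, 500))
  expect_equal(overlap_statistic(A, B, "count"),
               bitmap_overlap(A, B, chl, "count"))
  expect_equal(overlap_statistic(A, B, "length"),
               bitmap_overlap(A, B, chl, "length"))
})

test_that("the empirical test is calibrated, powered and reproducible", {
  chl <- c(chr1 = 1e6, chr2 = 1e6)
  set.seed(63)
  lm <- merge_intervals(tibble::tibble(
    chrom = sample(names(chl), 20, replace = TRUE),
    start = round(runif(20, 0, 9.5e5))
  ) |> dplyr::mutate(end = start + 10000))

  # independence: mean fold near 1 (analytic expectation; a single draw of
  # 20 small regions is noisy, so average over independent draws)
  folds <- vapply(1:25, function(i) {
    rg <- shuffle_regions(tibble::tibble(chrom = "chr1", start = 0,
                                         end = rep(5000, 50)), chl,
                          seed = 700 + i)
    empirical_enrichment(rg, lm, chl, mode = "length",
                         n_replicates = 200, seed = 800 + i)$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.15)
  rg <- shuffle_regions(tibble::tibble(chrom = "chr1", start = 0,
                                       end = rep(5000, 20)), chl, seed = 7)
  e <- empirical_enrichment(rg, lm, chl, mode = "length",
                            n_replicates = 1000, seed = 8)
  e2 <- empirical_enrichment(rg, lm, chl, mode = "length",
                             n_replicates = 1000, seed = 8)
  expect_identical(e$null, e2$null)

  # regions fully inside landmarks occupying ~10% of the genome
  inside <- tibble::tibble(chrom = lm$chrom[1:10], start = lm$start[1:10],
                           end = lm$start[1:10] + 5000)
  ep <- empirical_enrichment(inside, lm, chl, mode = "length",
                             n_replicates = 1000, seed = 9)
  expect_gt(ep$fold, 5)
  expect_equal(ep$empirical_p, 1 / 1001)

  # an observation below every null value has p near 1 (depletion)
  # and p is monotone non-increasing in the observed statistic when the
  # null is held fixed (same lengths, same seed)
  off <- tibble::tibble(chrom = "chr2", start = 0, end = 5000)
  lm_far <- tibble::tibble(chrom = "chr1", start = 0, end = 5e5)
  e_lo <- empirical_enrichment(off, lm_far, chl, mode = "length",
                               n_replicates = 500, seed = 10)
  in_lm <- tibble::tibble(chrom = "chr1", start = 0, end = 5000)
  e_hi <- empirical_enrichment(in_lm, lm_far, chl, mode = "length",
                               n_replicates = 500, seed = 10)
  expect_identical(e_lo$null, e_hi$null)
  expect_gt(e_hi$observed, e_lo$observed)
  expect_lte(e_hi$empirical_p, e_lo$empirical_p)
  expect_gt(e_lo$empirical_p, 0.5)

  expect_error(empirical_enrichment(rg, lm, chl, n_replicates = 10),
               class = "sdscape_invalid_spec")
  expect_error(empirical_enrichment(rg[0, ], lm, chl, n_replicates = 100),
               class = "sdscape_undefined_result")
})

test_that("gene-family enrichment detects planting and respects symmetry", {
  chl <- c(chr1 = 1e6, chr2 = 1e6)
  set.seed(67)
  sd_map <- merge_intervals(tibble::tibble(
    chrom = sample(names(chl), 15, replace = TRUE),
    start = round(runif(15, 0, 9e5))
  ) |> dplyr::mutate(end = start + 12000))

  # family genes planted inside SDs far above background
  fam <- tibble::tibble(chrom = sd_map$chrom[1:10],
                        start = sd_map$start[1:10] + 100,
                        end = sd_map$start[1:10] + 2100)
  for (mode in c("count", "length")) {
    ef <- gene_family_enrichment(sd_map, fam, chl, mode = mode,
                                 n_replicates = 1000, seed = 11)
    expect_gt(ef$fold, 2)
    expect_lte(ef$empirical_p, 0.01)
  }

  # identically placed family and non-family genes give the same fold
  ga <- tibble::tibble(chrom = "chr1", start = seq(0, 9e5, 1e5), end = NA)
  ga$end <- ga$start + 3000
  e_a <- gene_family_enrichment(sd_map, ga, chl, mode = "length",
                                n_replicates = 500, seed = 12)
  e_b <- gene_family_enrichment(sd_map, ga, chl, mode = "length",
                                n_replicates = 500, seed = 12)
  expect_equal(e_a$fold, e_b$fold)

  expect_error(gene_family_enrichment(sd_map, ga[0, ], chl),
               class = "sdscape_undefined_result")
})
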