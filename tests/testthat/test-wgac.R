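# Self-alignment stage: masking/excision round trips, detection thresholds,
# strand symmetry, high-copy cleaning, identity histogram.

test_that("repeat excision and coordinate lifting round-trip exactly", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), 250), collapse = ""
  )))
  rep_bed <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  m <- mask_repeats(g, rep_bed)
  expect_equal(Biostrings::width(m$genome)[[1]], 900)
  expect_equal(lift_interval(m$map, "chr1", 250, 251)$start, 350)
  # empty mask leaves the genome untouched
  m0 <- mask_repeats(g, NULL)
  expect_identical(as.character(m0$genome), as.character(g))
  # positions inside the excised repeat cannot be lifted forward
  expect_error(lift_position(m$map, "chr1", 150),
               class = "sdscape_invalid_spec")
  # round trip of a non-repeat position is the identity
  expect_equal(
    lift_interval(m$map, "chr1", lift_position(m$map, "chr1", 350),
                  lift_position(m$map, "chr1", 350) + 1)$start,
    350
  )
  # overlapping repeat records are merged with a warning
  expect_warning(
    mask_repeats(g, tibble::tibble(chrom = "chr1", start = c(100, 150),
                                   end = c(200, 250))),
    "merged"
  )
})

test_that("self-alignment finds planted duplications at the stated thresholds", {
  ev <- dplyr::bind_rows(
    duplication_event("kb12", "chr1", 2000, 3200, "chr1", 10000),
    duplication_event("bp800", "chr1", 15000, 15800, "chr1", 20000)
  )
  sim <- make_dup_genome(c(chr1 = 30000), ev)
  aln <- self_align(sim$reference)
  # the exact 1,200 bp pair is found once, at full identity and near-full length
  expect_equal(nrow(aln), 1)
  expect_equal(aln$identity, 1.0)
  expect_gte(aln$aligned_length, 0.95 * 1200)
  expect_equal(aln$chrom_a, "chr1")
  expect_lte(abs(aln$start_a - 2000), 50)
  # the 800 bp duplicate is below the 1 kb floor: absent by construction

  # 10 kb copy at 3% divergence: reported identity within 0.01 of the log
  ev2 <- duplication_event("kb10", "chr1", 2000, 12000, "chr1", 20000,
                           divergence = 0.03)
  sim2 <- make_dup_genome(c(chr1 = 40000), ev2, seed = 12)
  aln2 <- self_align(sim2$reference)
  expect_equal(nrow(aln2), 1)
  expect_lt(abs(aln2$identity - sim2$truth$events$realized_identity), 0.01)

  expect_error(self_align(sim$reference, k = 25),
               class = "sdscape_invalid_spec")
})

test_that("inverted duplications are reported on the minus strand", {
  g <- simulate_reference(genome_spec(c(chr1 = 20000), seed = 41))
  chars <- as.character(g)[["chr1"]]
  seg <- substr(chars, 2001, 4000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  substr(chars, 10001, 12000) <- rc
  g2 <- Biostrings::DNAStringSet(c(chr1 = chars))
  aln <- self_align(g2)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$strand, "-")
  expect_lte(abs(aln$start_a - 2000), 50)
  expect_lte(abs(aln$start_b - 10000), 50)
})

test_that("reverse-complementing the genome flips coordinates, not pairs", {
  ev <- dplyr::bind_rows(
    duplication_event("a", "chr1", 2000, 4000, "chr1", 10000, divergence = 0.02),
    duplication_event("b", "chr1", 15000, 16500, "chr1", 24000, divergence = 0.05)
  )
  sim <- make_dup_genome(c(chr1 = 30000), ev)
  aln <- self_align(sim$reference)
  grc <- Biostrings::reverseComplement(sim$reference)
  names(grc) <- names(sim$reference)
  aln_rc <- self_align(grc)
  L <- 30000
  flipped <- sdscape:::canonicalize_alignments(
    dplyr::mutate(aln_rc,
      start_a2 = L - .data$end_a, end_a2 = L - .data$start_a,
      start_b2 = L - .data$end_b, end_b2 = L - .data$start_b,
      start_a = .data$start_a2, end_a = .data$end_a2,
      start_b = .data$start_b2, end_b = .data$end_b2
    )[, names(aln)], stage = "initial"
  )
  expect_true(same_pair_sets(aln, flipped, slack = 50))
})

test_that("raising min_identity never increases the alignment count", {
  ev <- dplyr::bind_rows(lapply(1:4, function(i) {
    duplication_event(paste0("e", i), "chr1", 1000 + (i - 1) * 7000,
                      1000 + (i - 1) * 7000 + 2000,
                      "chr2", 2000 + (i - 1) * 6000,
                      divergence = c(0, 0.03, 0.06, 0.09)[i])
  }))
  sim <- make_dup_genome(c(chr1 = 40000, chr2 = 40000), ev, seed = 43)
  counts <- vapply(c(0.90, 0.93, 0.96, 0.99), function(t) {
    nrow(self_align(sim$reference, min_identity = t))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("high-copy and multi-chromosome families are cleaned, survivors kept", {
  # 60-copy family on one chromosome (edges connect all copies to the source)
  src <- fake_alignment("chr1", 0, 1500, "chr1", 0, 1500)[0, ]
  fam <- dplyr::bind_rows(lapply(1:60, function(i) {
    fake_alignment("chr1", 0, 1500, "chr1", i * 2000, i * 2000 + 1500,
                   stage = "initial")
  }))
  ctrl <- fake_alignment("chr2", 0, 2000, "chr2", 5000, 7000,
                         stage = "initial")
  tri <- dplyr::bind_rows(
    fake_alignment("chr3", 0, 2000, "chr4", 0, 2000, stage = "initial"),
    fake_alignment("chr3", 0, 2000, "chr5", 0, 2000, stage = "initial")
  )
  cleaned <- filter_high_copy(dplyr::bind_rows(fam, ctrl, tri))
  expect_equal(nrow(cleaned), 1)
  expect_equal(cleaned$chrom_a, "chr2")
  expect_equal(unique(cleaned$stage), "cleaned")

  # 49 copies on one chromosome: below both thresholds, retained
  fam49 <- dplyr::bind_rows(lapply(1:48, function(i) {
    fake_alignment("chr1", 0, 1500, "chr1", i * 2000, i * 2000 + 1500,
                   stage = "initial")
  }))
  expect_equal(nrow(filter_high_copy(fam49)), 48)

  # exactly 3 chromosomes triggers the chromosome rule
  expect_equal(nrow(filter_high_copy(tri)), 0)

  # idempotence and empty input
  expect_identical(filter_high_copy(cleaned), cleaned)
  expect_equal(nrow(filter_high_copy(ctrl[0, ])), 0)
})

test_that("identity histogram bins partition 90-100 and count correctly", {
  aln <- dplyr::bind_rows(
    fake_alignment("chr1", 0, 1000, "chr1", 2000, 3000, identity = 0.905),
    fake_alignment("chr1", 0, 1000, "chr1", 4000, 5000, identity = 0.915),
    fake_alignment("chr1", 0, 1000, "chr1", 6000, 7000, identity = 0.915)
  )
  h <- identity_histogram(aln)
  expect_equal(h$count[h$bin == 90], 1)
  expect_equal(h$count[h$bin == 91], 2)
  expect_equal(sum(h$count), 3)
  h0 <- identity_histogram(aln[0, ])
  expect_true(all(h0$count == 0))
  # identity 1.0 lands in the closed top bin
  h1 <- identity_histogram(fake_alignment("chr1", 0, 1000, "chr1", 2000, 3000,
                                          identity = 1.0))
  expect_equal(h1$count[h1$bin == 99], 1)
})

test_that("planted divergence cohorts produce histogram modes where expected", {
  ev <- dplyr::bind_rows(lapply(1:10, function(i) {
    dplyr::bind_rows(
      duplication_event(paste0("lo", i), "chr1", (i - 1) * 8000 + 1000,
                        (i - 1) * 8000 + 3000, "chr2", (i - 1) * 8000 + 1000,
                        divergence = 0.02),
      duplication_event(paste0("hi", i), "chr3", (i - 1) * 8000 + 1000,
                        (i - 1) * 8000 + 3000, "chr4", (i - 1) * 8000 + 1000,
                        divergence = 0.06)
    )
  }))
  sim <- make_dup_genome(
    c(chr1 = 82000, chr2 = 82000, chr3 = 82000, chr4 = 82000), ev, seed = 47
  )
  aln <- self_align(sim$reference)
  h <- identity_histogram(aln)
  top2 <- h$bin[order(-h$count)][1:2]
  expect_setequal(top2, c(94, 98))
})
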