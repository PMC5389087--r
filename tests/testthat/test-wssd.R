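# Read-depth stage: mapping semantics, window profiling, calibration,
# interval calling and copy-number estimation.

test_that("read placement follows the equal-best-split contract", {
  g <- simulate_reference(genome_spec(c(chr1 = 50000), seed = 51))
  gc <- as.character(g)[["chr1"]]

  # an error-free unique read maps exactly once, at its origin
  r1 <- Biostrings::DNAStringSet(substr(gc, 1001, 1036))
  p1 <- place_reads(r1, g)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$start, 1000)
  expect_equal(p1$weight, 1)
  expect_equal(p1$mismatches, 0)

  # a read from an exact duplicate is split equally between the two loci
  ev <- duplication_event("d", "chr1", 1000, 2200, "chr1", 30000)
  sim <- plant_duplications(g, ev, seed = 2)
  p2 <- place_reads(r1, sim$reference)
  expect_equal(nrow(p2), 2)
  expect_equal(sort(p2$start), c(1000, 30000))
  expect_equal(p2$weight, c(0.5, 0.5))

  # a read from a donor-only copy (divergence 0) lands on its source locus
  evd <- duplication_event("dd", "chr1", 5000, 6200, "chr1", NA,
                           in_reference = FALSE)
  simd <- plant_duplications(g, evd, seed = 3)
  donor_chars <- as.character(simd$donor$hap2)[["chr1"]]
  rd <- Biostrings::DNAStringSet(substr(donor_chars, 50001, 50036))
  pd <- place_reads(rd, simd$reference)
  expect_equal(pd$start, 5000)

  # three mismatches against every locus: dropped and counted
  bad <- strsplit(substr(gc, 1001, 1036), "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  for (i in c(5, 15, 25)) bad[i] <- flip(bad[i])
  pb <- place_reads(Biostrings::DNAStringSet(paste(bad, collapse = "")), g)
  expect_equal(nrow(pb), 0)
  expect_equal(attr(pb, "unmapped"), 1)

  # reverse-strand reads map back to the forward origin
  rr <- Biostrings::reverseComplement(r1)
  pr <- place_reads(rr, g)
  expect_equal(pr$start, 1000)
  expect_equal(pr$strand, "-")

  expect_warning(place_reads(Biostrings::DNAStringSet(character()), g),
                 "empty read set")
})

test_that("depth is conserved through mapping when error-free", {
  g <- simulate_reference(genome_spec(c(chr1 = 1e5), seed = 53))
  rs <- simulate_reads(g, depth = 5, error_rate = 0, seed = 4)
  pl <- place_reads(rs, g)
  # every read maps; split weights sum to the read count
  expect_equal(attr(pl, "unmapped"), 0)
  expect_equal(sum(pl$weight), length(rs$reads))
})

test_that("background calibration is accurate and robust to duplication", {
  g <- simulate_reference(genome_spec(c(chr1 = 4e5), seed = 57))
  rs <- simulate_reads(g, depth = 20, seed = 5)
  pl <- place_reads(rs, g)
  pr <- profile_depth(pl, g)
  expect_lt(abs(pr$background_mean - 20), 1)

  # duplicating 5% of the genome (donor-only extra copies) moves the
  # trimmed background by under 2%
  ev <- duplication_event("d", "chr1", 100000, 120000,
                          rep("chr1", 3), rep(NA_real_, 3),
                          divergence = 0.005, in_reference = FALSE)
  sim <- plant_duplications(g, ev, seed = 6)
  rs2 <- simulate_reads(sim$donor, depth = 10, seed = 5)
  pl2 <- place_reads(rs2, sim$reference)
  pr2 <- profile_depth(pl2, sim$reference)
  expect_lt(abs(pr2$background_mean - pr$background_mean) / pr$background_mean,
            0.02)

  # windows fully inside a masked repeat are uncallable
  reps <- tibble::tibble(chrom = "chr1", start = 200000, end = 210000)
  pr3 <- profile_depth(pl, g, repeats = reps)
  inside <- pr3$windows$start >= 201000 & pr3$windows$end <= 209000
  expect_true(all(!pr3$windows$callable[inside]))

  # fully repeat-masked genome cannot be calibrated
  allrep <- tibble::tibble(chrom = "chr1", start = 0, end = 4e5)
  expect_error(profile_depth(pl, g, repeats = allrep),
               class = "sdscape_calibration_error")
})

test_that("interval calling respects the 10 kb floor and recovers spans", {
  g <- simulate_reference(genome_spec(c(chr1 = 2e5, chr2 = 2e5), seed = 21))
  ev <- dplyr::bind_rows(
    duplication_event("small6k", "chr1", 50000, 56000,
                      rep("chr1", 2), rep(NA_real_, 2),
                      divergence = 0.005, in_reference = FALSE),
    duplication_event("big15k", "chr2", 80000, 95000,
                      rep("chr2", 3), rep(NA_real_, 3),
                      divergence = 0.005, in_reference = FALSE)
  )
  sim <- plant_duplications(g, ev, seed = 4)
  rs <- simulate_reads(sim$donor, depth = 10, seed = 5)
  pl <- place_reads(rs, sim$reference)
  pr <- profile_depth(pl, sim$reference, exclude = truth_intervals(sim$truth))
  iv <- call_wssd_intervals(pr)

  # the 6 kb excess region is never called
  expect_false(any(iv$chrom == "chr1"))
  # the 15 kb region yields one interval >= 10 kb covering >= 80% of it
  big <- iv[iv$chrom == "chr2", ]
  expect_equal(nrow(big), 1)
  expect_gte(big$end - big$start, 10000)
  planted <- tibble::tibble(chrom = "chr2", start = 80000, end = 95000)
  expect_gte(intersect_length(big, planted) / 15000, 0.8)

  # raising z never increases the total called length
  lens <- vapply(c(2, 3, 4, 6), function(z) {
    ivz <- call_wssd_intervals(pr, z = z)
    if (nrow(ivz) == 0) 0 else sum(ivz$end - ivz$start)
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))

  # an empty profile region yields no calls
  pr_quiet <- profile_depth(pl, sim$reference,
                            exclude = truth_intervals(sim$truth))
  expect_equal(nrow(call_wssd_intervals(pr_quiet, z = 50)), 0)
})

test_that("copy-number estimation is the diploid depth ratio", {
  # hand-built profile: constant coverage 75 against a background of 30
  cov <- list(chr1 = S4Vectors::Rle(75, 20000))
  prof <- structure(
    list(windows = tibble::tibble(), window = 5000, slide = 1000,
         background_mean = 30, background_sd = 1, coverage = cov,
         repeats = tibble::tibble(chrom = character(), start = double(),
                                  end = double()),
         chrom_lengths = c(chr1 = 20000), read_length = 36),
    class = "wssd_profile"
  )
  est <- estimate_copy_number(
    tibble::tibble(chrom = "chr1", start = 0, end = 12000), prof
  )
  expect_equal(est$copy_number, 5.0)

  # depth equal to background is the diploid baseline of 2
  prof$coverage$chr1 <- S4Vectors::Rle(30, 20000)
  est2 <- estimate_copy_number(
    tibble::tibble(chrom = "chr1", start = 0, end = 12000), prof
  )
  expect_equal(est2$copy_number, 2.0)

  prof_bad <- prof
  prof_bad$background_mean <- NA_real_
  expect_error(
    estimate_copy_number(tibble::tibble(chrom = "chr1", start = 0, end = 100),
                         prof_bad),
    class = "sdscape_calibration_error"
  )
})
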