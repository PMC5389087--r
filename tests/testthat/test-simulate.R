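# Synthetic-genome simulator: determinism, identity bookkeeping, coverage.

test_that("genome specs are validated and references are reproducible", {
  expect_error(genome_spec(c(chr1 = 5000)), class = "sdscape_invalid_spec")
  expect_error(genome_spec(c(1e5, 1e5)), class = "sdscape_invalid_spec")
  expect_error(genome_spec(c(chr1 = 1e5), gc_fraction = 1.2),
               class = "sdscape_invalid_spec")

  spec <- genome_spec(c(chr1 = 1e5), gc_fraction = 0.42, seed = 7)
  g1 <- simulate_reference(spec)
  g2 <- simulate_reference(spec)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(Biostrings::width(g1), 1e5)
  gc <- Biostrings::letterFrequency(g1, "GC", as.prob = TRUE)[1]
  expect_lt(abs(gc - 0.42), 0.02)

  # byte-identical FASTA on disk
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("planted copies respect the requested divergence exactly", {
  g <- simulate_reference(genome_spec(c(chr1 = 6e4), seed = 3))

  # zero divergence: exact substring duplicate
  ev0 <- duplication_event("e0", "chr1", 1000, 3000, "chr1", 10000)
  sim0 <- plant_duplications(g, ev0, seed = 2)
  ref <- as.character(sim0$reference)[["chr1"]]
  expect_identical(substr(ref, 10001, 12000), substr(ref, 1001, 3000))
  expect_equal(sim0$truth$events$expected_identity, 1.0)
  expect_equal(sim0$truth$events$realized_identity, 1.0)

  # 3% divergence on a 10 kb copy: realized Hamming identity near 0.97
  ev3 <- duplication_event("e3", "chr1", 1000, 11000, "chr1", 30000,
                           divergence = 0.03)
  sim3 <- plant_duplications(g, ev3, seed = 2)
  tr <- sim3$truth$events
  expect_gte(tr$realized_identity, 0.965)
  expect_lte(tr$realized_identity, 0.975)
  # mutation log agrees with direct Hamming comparison of the sequences
  ref3 <- as.character(sim3$reference)[["chr1"]]
  src <- strsplit(substr(ref3, 1001, 11000), "")[[1]]
  cpy <- strsplit(substr(ref3, 30001, 40000), "")[[1]]
  expect_equal(mean(src == cpy), tr$realized_identity)
})

test_that("many-copy events are all placed and collisions are errors", {
  g <- simulate_reference(genome_spec(c(chr1 = 2e5, chr2 = 2e5), seed = 5))
  starts <- seq(10000, 190000, length.out = 30)
  ev <- dplyr::bind_rows(
    duplication_event("big", "chr1", 1000, 2500,
                      copy_chrom = rep(c("chr1", "chr2"), each = 30),
                      copy_start = round(c(starts + 2500, starts))),
    duplication_event("ctrl", "chr2", 1000, 3000, "chr2", 5000)
  )
  sim <- plant_duplications(g, ev, seed = 9)
  big <- sim$truth$events[sim$truth$events$event_id == "big", ]
  expect_equal(nrow(big), 60)
  expect_equal(nrow(merge_intervals(big)), 60) # no two copies merged

  clash <- duplication_event("x", "chr1", 1000, 3000,
                             c("chr1", "chr1"), c(10000, 11000))
  expect_error(plant_duplications(g, clash, seed = 1),
               class = "sdscape_placement_error")
})

test_that("donor-only copies never alter the reference", {
  g <- simulate_reference(genome_spec(c(chr1 = 5e4), seed = 13))
  ev <- duplication_event("d", "chr1", 2000, 4000, "chr1", NA,
                          divergence = 0.01, in_reference = FALSE)
  sim <- plant_duplications(g, ev, seed = 4)
  expect_identical(as.character(sim$reference), as.character(g))
  # but the donor haplotype B carries the extra copy
  expect_equal(Biostrings::width(sim$donor$hap2)[[1]], 5e4 + 2000)
  expect_equal(Biostrings::width(sim$donor$hap1)[[1]], 5e4)
})

test_that("artifact copies are excised from both donor haplotypes", {
  g <- simulate_reference(genome_spec(c(chr1 = 5e4, chr2 = 5e4), seed = 17))
  ev <- duplication_event("a", "chr1", 2000, 4000, "chr2", 10000,
                          in_donor = FALSE)
  sim <- plant_duplications(g, ev, seed = 4)
  expect_equal(Biostrings::width(sim$reference)[[2]], 5e4)
  expect_equal(Biostrings::width(sim$donor$hap1)[[2]], 5e4 - 2000)
  expect_equal(Biostrings::width(sim$donor$hap2)[[2]], 5e4 - 2000)
})

test_that("repeat families are validated, dispersed and reproducible", {
  g <- simulate_reference(genome_spec(c(chr1 = 1e5, chr2 = 1e5, chr3 = 1e5),
                                      seed = 19))
  expect_error(plant_repeats(g, 300, 10), class = "sdscape_invalid_spec")
  expect_error(plant_repeats(g, 50, 100), class = "sdscape_invalid_spec")

  r1 <- plant_repeats(g, 300, 200, seed = 8)
  expect_equal(nrow(r1$repeats), 200)
  expect_gte(length(unique(r1$repeats$chrom)), 3)
  expect_true(all(r1$repeats$end - r1$repeats$start == 300))
  r2 <- plant_repeats(g, 300, 200, seed = 8)
  expect_identical(r1$repeats, r2$repeats)
})

test_that("read simulation conserves coverage and honours the error model", {
  g <- simulate_reference(genome_spec(c(chr1 = 1e6), seed = 23))
  expect_error(simulate_reads(g, depth = 0), class = "sdscape_invalid_spec")
  expect_error(simulate_reads(g, depth = 1, error_rate = 0.5),
               class = "sdscape_invalid_spec")
  expect_error(
    simulate_reads(simulate_reference(genome_spec(c(c1 = 1e4), seed = 1)),
                   depth = 1, read_length = 20000),
    class = "sdscape_invalid_spec"
  )

  rs <- simulate_reads(g, depth = 20, read_length = 36, error_rate = 0,
                       seed = 6)
  expect_lte(abs(length(rs$reads) - 20 * 1e6 / 36), 1)
  # total read bases = depth * genome length within rounding
  expect_lte(abs(sum(Biostrings::width(rs$reads)) - 20 * 1e6), 36)

  # with error_rate 0 every read matches its origin exactly
  gc <- as.character(g)[["chr1"]]
  idx <- sample(length(rs$reads), 200)
  for (i in idx) {
    o <- rs$origins[i, ]
    frag <- substr(gc, o$start + 1, o$start + 36)
    rd <- as.character(rs$reads[[i]])
    if (o$strand == "-") {
      rd <- as.character(Biostrings::reverseComplement(rs$reads[[i]]))
    }
    expect_identical(rd, frag)
  }

  # per-base coverage over a unique 10 kb window is near the target depth
  cov <- IRanges::coverage(
    IRanges::IRanges(start = rs$origins$start + 1, width = 36), width = 1e6
  )
  win <- mean(as.numeric(S4Vectors::window(cov, 500001, 510000)))
  expect_lt(abs(win - 20), 3)

  # determinism: same seed, byte-identical FASTQ
  rs2 <- simulate_reads(g, depth = 20, read_length = 36, error_rate = 0,
                        seed = 6)
  expect_identical(as.character(rs$reads), as.character(rs2$reads))

  # error injection changes roughly error_rate of bases
  rse <- simulate_reads(g, depth = 2, read_length = 36, error_rate = 0.01,
                        seed = 7)
  rs0 <- simulate_reads(g, depth = 2, read_length = 36, error_rate = 0,
                        seed = 7)
  diff <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 as.character(rse$reads[1:2000]), as.character(rs0$reads[1:2000]))
  expect_lt(abs(mean(diff) / 36 - 0.01), 0.003)
})

test_that("truth JSON round-trips", {
  g <- simulate_reference(genome_spec(c(chr1 = 5e4), seed = 29))
  ev <- duplication_event("e", "chr1", 2000, 4000, "chr1", 10000,
                          divergence = 0.02)
  sim <- plant_duplications(g, ev, seed = 3)
  p <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, p)
  back <- read_truth_json(p)
  expect_equal(back$events$realized_identity,
               sim$truth$events$realized_identity)
  expect_equal(back$chrom_lengths, sim$truth$chrom_lengths)
})
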