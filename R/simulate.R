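# Synthetic genome simulator: reference genomes, planted duplications and
# high-copy repeats, donor haplotypes carrying extra copies, and uniform
# coverage short reads -- all with exact ground truth so the detection
# stages are testable without external data.

DNA_BASES <- c("A", "C", "G", "T")

#' Specify a synthetic reference genome
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp),
#'   all at least 10 kb, names unique.
#' @param gc_fraction Genome GC proportion in (0, 1).
#' @param seed Integer seed; the same spec and seed always reproduce the
#'   identical genome.
#' @return A `genome_spec` object.
#' @export
#' @examples
#' genome_spec(c(chr1 = 1e5), gc_fraction = 0.42, seed = 7)
genome_spec <- function(chrom_lengths, gc_fraction = 0.41, seed = 1) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths))) {
    stop_invalid("chromosome names must be present and unique")
  }
  if (any(chrom_lengths < 10000)) {
    stop_invalid("all chromosome lengths must be >= 10,000 bp")
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop_invalid("gc_fraction must lie in (0, 1)")
  }
  structure(
    list(chrom_lengths = chrom_lengths, gc_fraction = gc_fraction,
         seed = as.integer(seed)),
    class = "genome_spec"
  )
}

#' Generate a random reference genome
#'
#' Draws i.i.d. nucleotides per chromosome at the spec's GC fraction.
#' Deterministic given the spec's seed.
#'
#' @param spec A [genome_spec()].
#' @return A `DNAStringSet`, one sequence per chromosome.
#' @export
simulate_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  gc <- spec$gc_fraction
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- with_seed(spec$seed, {
    vapply(spec$chrom_lengths, function(n) {
      paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  Biostrings::DNAStringSet(setNames(seqs, names(spec$chrom_lengths)))
}

#' Describe one duplication event as copy rows
#'
#' An event has one source interval and one or more copies. Copies flagged
#' `in_reference` are written into the reference assembly; copies with
#' `in_reference = FALSE` exist only in the donor individual's genome
#' (appended to the donor haplotype) and create excess read depth at the
#' source locus. `in_reference = TRUE, in_donor = FALSE` models an
#' assembly artifact: the assembly carries a copy the sequenced individual
#' does not have.
#'
#' @param event_id Event label.
#' @param src_chrom,src_start,src_end Source interval (0-based half-open).
#' @param copy_chrom,copy_start Vectors giving each copy's target position
#'   (reference coordinates). Use `NA` start for donor-only copies; they
#'   are appended at the end of `copy_chrom` in the donor haplotype.
#' @param divergence Per-copy substitution proportion in \[0, 0.12\]
#'   (recycled).
#' @param mode `"tandem"`, `"intrachromosomal"` or `"interchromosomal"`
#'   (recycled; bookkeeping only).
#' @param in_reference,in_donor Logical flags per copy (recycled).
#' @return Tibble with one row per copy.
#' @export
duplication_event <- function(event_id, src_chrom, src_start, src_end,
                              copy_chrom, copy_start,
                              divergence = 0, mode = "intrachromosomal",
                              in_reference = TRUE, in_donor = TRUE) {
  n <- length(copy_chrom)
  len <- src_end - src_start
  tibble(
    event_id = event_id,
    src_chrom = src_chrom, src_start = src_start, src_end = src_end,
    chrom = copy_chrom,
    start = as.double(copy_start),
    end = as.double(copy_start) + len,
    divergence = rep_len(divergence, n),
    mode = rep_len(mode, n),
    in_reference = rep_len(in_reference, n),
    in_donor = rep_len(in_donor, n)
  )
}

validate_events <- function(events, chrom_lengths) {
  events <- as_tibble(events)
  need <- c("event_id", "src_chrom", "src_start", "src_end", "chrom",
            "start", "end", "divergence", "mode", "in_reference", "in_donor")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) {
    stop_invalid(paste("event table missing columns:", paste(miss, collapse = ", ")))
  }
  if (any(events$src_end - events$src_start < 200)) {
    stop_invalid("every source interval must be >= 200 bp")
  }
  if (any(events$divergence < 0 | events$divergence > 0.12)) {
    stop_invalid("per-copy divergence must lie in [0, 0.12]")
  }
  ref_rows <- events[events$in_reference, , drop = FALSE]
  if (nrow(ref_rows) > 0) {
    bad <- !(ref_rows$chrom %in% names(chrom_lengths)) |
      is.na(ref_rows$start) | ref_rows$start < 0 |
      ref_rows$end > chrom_lengths[ref_rows$chrom]
    if (any(bad)) {
      stop_invalid("reference-space copy intervals must fit their chromosomes")
    }
  }
  # reference-space footprint: sources plus in_reference copies must be
  # mutually disjoint, or the planted sequences would overwrite each other
  srcs <- distinct(events, .data$event_id, .data$src_chrom, .data$src_start,
                   .data$src_end)
  foot <- bind_rows(
    tibble(chrom = srcs$src_chrom, start = srcs$src_start, end = srcs$src_end,
           what = paste0(srcs$event_id, ":source")),
    tibble(chrom = ref_rows$chrom, start = ref_rows$start, end = ref_rows$end,
           what = paste0(ref_rows$event_id, ":copy"))
  )
  foot <- arrange(foot, .data$chrom, .data$start)
  if (nrow(foot) > 1) {
    same <- foot$chrom[-1] == foot$chrom[-nrow(foot)]
    clash <- same & (foot$start[-1] < foot$end[-nrow(foot)])
    if (any(clash)) {
      i <- which(clash)[1]
      stop_placement(paste0(
        "planted intervals collide: ", foot$what[i], " [", foot$start[i], ",",
        foot$end[i], ") overlaps ", foot$what[i + 1], " [", foot$start[i + 1],
        ",", foot$end[i + 1], ") on ", foot$chrom[i]
      ))
    }
  }
  events
}

# Apply i.i.d. substitutions at `rate` to a sequence string; returns the
# mutated string and the number of substitutions actually applied.
mutate_sequence <- function(x, rate) {
  n <- nchar(x)
  if (rate <= 0 || n == 0) return(list(seq = x, n_sub = 0L))
  pos <- which(runif(n) < rate)
  if (length(pos) == 0) return(list(seq = x, n_sub = 0L))
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  for (i in pos) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  list(seq = paste(chars, collapse = ""), n_sub = length(pos))
}

#' Plant duplication events into a genome
#'
#' Each copy is its source sequence with substitutions applied at i.i.d.
#' positions at the copy's divergence rate. Copies flagged `in_reference`
#' are written into the returned reference; donor-only copies are appended
#' to the donor haplotype and never alter the reference. The donor is
#' returned as two haplotypes (the sequenced individual is diploid): hap A
#' is the reference minus assembly-artifact copies, hap B additionally
#' carries the donor-only copies.
#'
#' @param genome Reference `DNAStringSet` (background sequence).
#' @param events Event/copy table from [duplication_event()] (rows may be
#'   concatenated across events with [dplyr::bind_rows()]).
#' @param seed Integer seed for the substitution draws.
#' @return A list of class `sd_sim`: `reference` (DNAStringSet), `donor`
#'   (list of two haplotype DNAStringSets), `truth` (an `sd_truth`).
#' @export
plant_duplications <- function(genome, events, seed = 1) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  chrom_lengths <- chrom_lengths_of(genome)
  events <- validate_events(events, chrom_lengths)

  ref <- as.character(genome)
  truth_rows <- vector("list", nrow(events))

  with_seed(seed, {
    # reference-space copies first (donor haplotypes inherit them)
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      src_seq <- substr(ref[[ev$src_chrom]], ev$src_start + 1, ev$src_end)
      mut <- mutate_sequence(src_seq, ev$divergence)
      len <- nchar(src_seq)
      if (ev$in_reference) {
        substr(ref[[ev$chrom]], ev$start + 1, ev$end) <- mut$seq
      }
      truth_rows[[i]] <- mutate(ev,
        genome = if (ev$in_reference) "reference" else "donor",
        copy_seq = mut$seq,
        n_sub = mut$n_sub,
        realized_identity = 1 - mut$n_sub / len,
        expected_identity = 1 - ev$divergence
      )
    }
  })
  truth <- bind_rows(truth_rows)

  # hap A: the individual's reference-like haplotype; artifact copies
  # (in assembly, not in individual) are excised
  hap_a <- ref
  artifacts <- truth[truth$in_reference & !truth$in_donor, , drop = FALSE]
  if (nrow(artifacts) > 0) {
    for (ch in unique(artifacts$chrom)) {
      cuts <- artifacts[artifacts$chrom == ch, , drop = FALSE]
      cuts <- cuts[order(-cuts$start), , drop = FALSE]
      s <- hap_a[[ch]]
      for (j in seq_len(nrow(cuts))) {
        s <- paste0(substr(s, 1, cuts$start[j]),
                    substr(s, cuts$end[j] + 1, nchar(s)))
      }
      hap_a[[ch]] <- s
    }
  }

  # hap B: hap A plus donor-only copies appended at chromosome ends;
  # record the realized donor coordinates in the truth table
  hap_b <- hap_a
  donor_only <- which(!truth$in_reference & truth$in_donor)
  for (i in donor_only) {
    ch <- truth$chrom[i]
    if (!ch %in% names(hap_b)) {
      stop_invalid(paste0("donor-only copy names unknown chromosome ", ch))
    }
    at <- nchar(hap_b[[ch]])
    hap_b[[ch]] <- paste0(hap_b[[ch]], truth$copy_seq[i])
    truth$start[i] <- at
    truth$end[i] <- at + nchar(truth$copy_seq[i])
  }

  truth <- select(truth, -"copy_seq")
  out_truth <- structure(
    list(events = truth, repeats = tibble(chrom = character(), start = double(),
                                          end = double(), name = character()),
         chrom_lengths = chrom_lengths),
    class = "sd_truth"
  )
  structure(
    list(
      reference = Biostrings::DNAStringSet(ref),
      donor = list(hap1 = Biostrings::DNAStringSet(hap_a),
                   hap2 = Biostrings::DNAStringSet(hap_b)),
      truth = out_truth
    ),
    class = "sd_sim"
  )
}

#' Reference-space intervals that are truly duplicated
#'
#' Returns the merged reference intervals involved in duplication, i.e.
#' sources and `in_reference` copies of the selected events.
#'
#' @param truth An `sd_truth`.
#' @param events Optional subset of event ids.
#' @return Merged interval tibble.
#' @export
truth_intervals <- function(truth, events = NULL) {
  stopifnot(inherits(truth, "sd_truth"))
  ev <- truth$events
  if (!is.null(events)) ev <- ev[ev$event_id %in% events, , drop = FALSE]
  src <- distinct(ev, .data$event_id, .data$src_chrom, .data$src_start,
                  .data$src_end)
  refcopies <- ev[ev$in_reference, , drop = FALSE]
  merge_intervals(bind_rows(
    tibble(chrom = src$src_chrom, start = src$src_start, end = src$src_end),
    tibble(chrom = refcopies$chrom, start = refcopies$start, end = refcopies$end)
  ))
}

#' Plant a high-copy interspersed repeat family
#'
#' Disperses `n_copies` mutated copies of a random consensus element over
#' the genome (at least 3 chromosomes when 3 exist), overwriting background
#' sequence. The returned BED serves as the known-repeat mask for the
#' alignment stage.
#'
#' @param genome Reference `DNAStringSet`.
#' @param family_length Element length in bp, within \[100, 1000\].
#' @param n_copies Number of copies, at least 50.
#' @param divergence Per-copy substitution rate from the consensus.
#' @param seed Integer seed.
#' @param avoid Optional interval tibble the copies must not touch.
#' @param name Family name written to the BED `name` column.
#' @return List with `genome` (modified `DNAStringSet`) and `repeats`
#'   (interval tibble with `name` and `copy` columns).
#' @export
plant_repeats <- function(genome, family_length, n_copies, divergence = 0.02,
                          seed = 1, avoid = NULL, name = "repfam1") {
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (family_length < 100 || family_length > 1000) {
    stop_invalid("family_length must lie in [100, 1000] bp")
  }
  if (n_copies < 50) {
    stop_invalid("a high-copy family needs n_copies >= 50")
  }
  chrom_lengths <- chrom_lengths_of(genome)
  chroms <- names(chrom_lengths)
  ref <- as.character(genome)
  occupied <- if (is.null(avoid)) {
    tibble(chrom = character(), start = double(), end = double())
  } else {
    check_intervals(avoid)[, c("chrom", "start", "end")]
  }

  placed <- with_seed(seed, {
    consensus <- paste(sample(DNA_BASES, family_length, replace = TRUE),
                       collapse = "")
    # guarantee dispersal: first copies go round-robin over the largest
    # chromosomes, the rest are drawn proportional to length
    ord <- order(-chrom_lengths)
    forced <- chroms[ord][seq_len(min(length(chroms), 3, n_copies))]
    rows <- vector("list", n_copies)
    for (i in seq_len(n_copies)) {
      ok <- FALSE
      for (try in seq_len(1000)) {
        ch <- if (i <= length(forced)) forced[i] else {
          sample(chroms, 1, prob = chrom_lengths)
        }
        room <- chrom_lengths[[ch]] - family_length
        if (room < 1) next
        s <- floor(runif(1) * room)
        cand <- tibble(chrom = ch, start = s, end = s + family_length)
        if (intersect_length(cand, occupied) == 0) {
          mut <- mutate_sequence(consensus, divergence)
          substr(ref[[ch]], s + 1, s + family_length) <- mut$seq
          rows[[i]] <- mutate(cand, name = name, copy = i)
          occupied <- bind_rows(occupied, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop_placement(paste0("could not place repeat copy ", i,
                              " without overlap; genome too small"))
      }
    }
    bind_rows(rows)
  })
  list(
    genome = Biostrings::DNAStringSet(ref),
    repeats = arrange(placed, .data$chrom, .data$start)
  )
}

new_read_set <- function(reads, read_length, depth, origins = NULL,
                         error_rate = NA_real_) {
  structure(
    list(reads = reads, read_length = read_length, depth = depth,
         error_rate = error_rate, origins = origins),
    class = "read_set"
  )
}

#' Simulate uniform-coverage short reads
#'
#' Draws read start positions uniformly over the supplied genome (a single
#' haplotype, or a list of haplotypes for a diploid donor -- `depth` is
#' fold-coverage of the concatenated set, so a diploid pair at `depth = d`
#' gives unique reference loci about `d` total coverage when each haplotype
#' receives `d/2`). Strand is random; substitution errors are applied per
#' base at `error_rate`.
#'
#' @param genomes A `DNAStringSet` or a (optionally named) list of
#'   `DNAStringSet` haplotypes.
#' @param depth Mean fold-coverage over the concatenated input, > 0.
#' @param read_length Read length in bp (default 36).
#' @param error_rate Per-base substitution error rate in \[0, 0.02\].
#' @param seed Integer seed.
#' @return A `read_set`: reads (`DNAStringSet`), origin table
#'   (haplotype, chrom, 0-based start, strand), parameters.
#' @export
simulate_reads <- function(genomes, depth, read_length = 36,
                           error_rate = 0.005, seed = 1) {
  if (methods::is(genomes, "DNAStringSet")) genomes <- list(hap1 = genomes)
  if (is.null(names(genomes))) {
    names(genomes) <- paste0("hap", seq_along(genomes))
  }
  if (depth <= 0) stop_invalid("depth must be positive")
  if (error_rate < 0 || error_rate > 0.02) {
    stop_invalid("error_rate must lie in [0, 0.02]")
  }
  units <- bind_rows(imap(genomes, function(g, hap) {
    tibble(hap = hap, chrom = names(g), len = as.double(Biostrings::width(g)))
  }))
  if (read_length > min(units$len)) {
    stop_invalid("read_length exceeds the shortest chromosome")
  }
  seq_chars <- unlist(lapply(genomes, as.character), use.names = FALSE)
  total_len <- sum(units$len)
  n_reads <- round(depth * total_len / read_length)
  feasible <- units$len - read_length + 1

  out <- with_seed(seed, {
    u <- sample.int(nrow(units), n_reads, replace = TRUE, prob = feasible)
    start0 <- floor(runif(n_reads) * feasible[u])
    raw <- substring(seq_chars[u], start0 + 1, start0 + read_length)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    sq <- Biostrings::DNAStringSet(raw)
    neg <- strand == "-"
    if (any(neg)) {
      sq[neg] <- Biostrings::reverseComplement(sq[neg])
    }
    seqs <- cpp_add_errors(as.character(sq), error_rate)
    list(seqs = seqs, u = u, start0 = start0, strand = strand)
  })

  reads <- Biostrings::DNAStringSet(out$seqs)
  names(reads) <- paste0("r", seq_len(n_reads))
  new_read_set(
    reads,
    read_length = read_length, depth = depth, error_rate = error_rate,
    origins = tibble(
      hap = units$hap[out$u], chrom = units$chrom[out$u],
      start = out$start0, strand = out$strand
    )
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", length(x$reads), " reads x ", x$read_length, " bp",
      if (!is.na(x$depth)) paste0(" (", x$depth, "x over input)"), "\n", sep = "")
  invisible(x)
}

#' @export
print.sd_sim <- function(x, ...) {
  cat("<sd_sim> reference:", length(x$reference), "chromosomes;",
      nrow(x$truth$events), "planted copies\n")
  invisible(x)
}

#' Write / read simulator ground truth as JSON
#'
#' @param truth An `sd_truth`.
#' @param path JSON path.
#' @return `read_truth_json()` returns an `sd_truth`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sd_truth"))
  jsonlite::write_json(
    list(events = truth$events, repeats = truth$repeats,
         chrom_lengths = as.list(truth$chrom_lengths)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(events = as_tibble(x$events), repeats = as_tibble(x$repeats),
         chrom_lengths = unlist(x$chrom_lengths)),
    class = "sd_truth"
  )
}
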