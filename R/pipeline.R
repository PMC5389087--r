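# End-to-end orchestration: run configuration, canonical synthetic fixtures,
# the full WGAC -> WSSD -> combine -> enrich -> genes pipeline, and the run
# manifest that makes a run reproducible bit for bit.

#' Pipeline run configuration
#'
#' Collects every stage parameter with its default. Inputs may be file
#' paths or in-memory objects (`DNAStringSet`, `read_set`, tibbles).
#'
#' @param genome Reference FASTA path or `DNAStringSet`.
#' @param reads FASTQ path or `read_set`.
#' @param repeats Repeat BED path or tibble (optional; without it the
#'   alignment stage runs unmasked, with a warning).
#' @param genes Gene annotation TSV/BED path or tibble (optional).
#' @param centromeres Named vector of centromere positions, or TSV path
#'   with columns chrom, position (optional; enables the enrichment stage).
#' @param outdir Output directory.
#' @param min_len,min_identity,k WGAC thresholds (1 kb, 0.90, seed 14).
#' @param max_copies,max_chroms Cleaning rule (50 copies / 3 chromosomes).
#' @param window,slide,z,wssd_min_len,max_mismatches WSSD parameters
#'   (5 kb/1 kb windows, z = 3, 10 kb floor, 2 mismatches).
#' @param cut,min_support Combination rule (0.94 identity, 0.5 support).
#' @param flank,short_chrom_flank,short_chroms Landmark geometry (2 Mb,
#'   300 kb).
#' @param n_replicates Permutation replicates (10,000).
#' @param seed Global seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
sd_config <- function(genome = NULL, reads = NULL, repeats = NULL,
                      genes = NULL, centromeres = NULL,
                      outdir = tempfile("sdscape_run_"),
                      min_len = 1000, min_identity = 0.90, k = 14,
                      max_copies = 50, max_chroms = 3,
                      window = 5000, slide = 1000, z = 3,
                      wssd_min_len = 10000, max_mismatches = 2,
                      cut = 0.94, min_support = 0.5,
                      flank = 2e6, short_chrom_flank = 3e5,
                      short_chroms = character(),
                      n_replicates = 10000, seed = 1) {
  structure(
    list(
      genome = genome, reads = reads, repeats = repeats, genes = genes,
      centromeres = centromeres, outdir = outdir,
      min_len = min_len, min_identity = min_identity, k = k,
      max_copies = max_copies, max_chroms = max_chroms,
      window = window, slide = slide, z = z, wssd_min_len = wssd_min_len,
      max_mismatches = max_mismatches, cut = cut, min_support = min_support,
      flank = flank, short_chrom_flank = short_chrom_flank,
      short_chroms = short_chroms, n_replicates = n_replicates,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match [sd_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sd_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop_invalid(paste("unknown config keys:", paste(bad, collapse = ", ")))
  }
  do.call(sd_config, vals)
}

log_stage <- function(...) {
  inform(paste0("[", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "] ", ...))
}

# --------------------------------------------------------------------------
# canonical fixtures

# Allocate `n` non-overlapping intervals by rejection sampling. `occupied`
# grows across calls through the enclosing environment of the returned
# closure.
make_allocator <- function(chrom_lengths, margin = 1000) {
  occupied <- tibble(chrom = character(), start = double(), end = double())
  chroms <- names(chrom_lengths)
  alloc <- function(len, chrom = NULL, not_chrom = NULL, max_tries = 2000) {
    for (t in seq_len(max_tries)) {
      ch <- chrom %||% {
        pool <- setdiff(chroms, not_chrom)
        if (length(pool) == 1) pool else sample(pool, 1, prob = chrom_lengths[pool])
      }
      room <- chrom_lengths[[ch]] - len
      if (room < 1) next
      s <- floor(runif(1) * room)
      cand <- tibble(chrom = ch, start = s, end = s + len)
      pad <- mutate(cand, start = pmax(0, .data$start - margin),
                    end = .data$end + margin)
      if (intersect_length(pad, occupied) == 0) {
        occupied <<- bind_rows(occupied, cand)
        return(cand)
      }
    }
    stop_placement("fixture allocator ran out of space")
  }
  reserve <- function(x) occupied <<- bind_rows(occupied, check_intervals(x))
  list(alloc = alloc, reserve = reserve,
       occupied = function() occupied)
}

# Event plan for the regular (expected-in-map) duplications: one reference
# copy each, donor-only extras so high-identity events carry depth support.
plan_regular_events <- function(n, alloc, max_len = 50000) {
  lens <- round(exp(seq(log(1000), log(max_len), length.out = n)))
  divs <- seq(0.10, 0, length.out = n) # biggest events most identical
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    len <- lens[n - i + 1] # descending lengths for easier packing
    dv <- divs[n - i + 1]
    mode <- c("tandem", "intrachromosomal", "interchromosomal")[(i %% 3) + 1]
    if (mode == "tandem") {
      slot <- alloc$alloc(2 * len)
      src <- mutate(slot, end = .data$start + len)
      cpy <- tibble(chrom = slot$chrom, start = src$end, end = slot$end)
    } else if (mode == "intrachromosomal") {
      src <- alloc$alloc(len)
      cpy <- alloc$alloc(len, chrom = src$chrom)
    } else {
      src <- alloc$alloc(len)
      cpy <- alloc$alloc(len, not_chrom = src$chrom)
    }
    n_extra <- if (dv <= 0.06) 2 + (i %% 3) else i %% 2
    copies <- bind_rows(
      mutate(cpy, in_reference = TRUE),
      if (n_extra > 0) {
        tibble(chrom = rep(src$chrom, n_extra), start = NA_real_,
               end = NA_real_, in_reference = FALSE)
      }
    )
    rows[[i]] <- tibble(
      event_id = sprintf("ev%02d", i),
      src_chrom = src$chrom, src_start = src$start, src_end = src$end,
      chrom = copies$chrom, start = copies$start,
      end = if_else(copies$in_reference, copies$end, NA_real_),
      divergence = dv, mode = mode,
      in_reference = copies$in_reference, in_donor = TRUE,
      expect_in_map = TRUE
    )
  }
  bind_rows(rows)
}

#' Generate a canonical synthetic test dataset
#'
#' Builds the packaged synthetic genome with planted duplications, repeat
#' family, donor haplotypes and reads, plus full ground truth.
#'
#' Scales:
#' * `small`: 3 chromosomes of 350 kb, 8 duplication events, a 60-copy
#'   repeat family, diploid 20x 36 bp reads.
#' * `standard`: 5 chromosomes of 1 Mb, 30 regular events (lengths 1--50
#'   kb, identities 0.90--1.00, donor-only extra copies on high-identity
#'   events), a 60-copy segmental family, a 3-chromosome family, two
#'   assembly-artifact events, a 200-copy interspersed repeat family, and
#'   diploid 20x 36 bp reads.
#'
#' Events planted to exercise the cleaning/validation filters (the 60-copy
#' family, the 3-chromosome family, artifact events) carry
#' `expect_in_map = FALSE` in the truth table.
#'
#' @param outdir Optional directory; when given, FASTA/FASTQ/BED/JSON files
#'   are written and their paths returned under `paths`.
#' @param scale `"small"` or `"standard"`.
#' @param seed Integer seed; everything derives from it.
#' @param depth Diploid fold-coverage of the simulated reads (default 20).
#' @return List: `reference`, `donor` (two haplotypes), `truth`,
#'   `repeats`, `reads`, `centromeres`, and `paths` when `outdir` given.
#' @export
make_fixture <- function(outdir = NULL, scale = c("small", "standard"),
                         seed = 1, depth = 20) {
  scale <- match.arg(scale)
  if (scale == "small") {
    chrom_lengths <- setNames(rep(350000, 3), paste0("chr", 1:3))
    n_events <- 8
    n_repeats <- 60
    with_family <- FALSE
  } else {
    chrom_lengths <- setNames(rep(1e6, 5), paste0("chr", 1:5))
    n_events <- 30
    n_repeats <- 200
    with_family <- TRUE
  }

  spec <- genome_spec(chrom_lengths, gc_fraction = 0.41,
                      seed = derive_seed(seed, "reference"))
  genome <- simulate_reference(spec)

  reps <- plant_repeats(genome, family_length = 300, n_copies = n_repeats,
                        divergence = 0.02, seed = derive_seed(seed, "repeats"))
  genome <- reps$genome

  events <- with_seed(derive_seed(seed, "plan"), {
    alloc <- make_allocator(chrom_lengths)
    alloc$reserve(reps$repeats)
    ev <- plan_regular_events(n_events, alloc,
                              max_len = if (scale == "small") 15000 else 50000)
    if (with_family) {
      # 60-copy family on two chromosomes: removed by the 50-copy rule
      fam_src <- alloc$alloc(1500, chrom = "chr1")
      fam_copies <- bind_rows(lapply(1:60, function(j) {
        alloc$alloc(1500, chrom = if (j %% 2 == 0) "chr1" else "chr2")
      }))
      fam <- tibble(
        event_id = "highcopy", src_chrom = fam_src$chrom,
        src_start = fam_src$start, src_end = fam_src$end,
        chrom = fam_copies$chrom, start = fam_copies$start,
        end = fam_copies$end, divergence = 0.01,
        mode = "intrachromosomal", in_reference = TRUE, in_donor = TRUE,
        expect_in_map = FALSE
      )
      # 3-chromosome family: removed by the chromosome rule
      tri_src <- alloc$alloc(2000, chrom = "chr3")
      tri_copies <- bind_rows(alloc$alloc(2000, chrom = "chr4"),
                              alloc$alloc(2000, chrom = "chr5"))
      tri <- tibble(
        event_id = "trichrom", src_chrom = tri_src$chrom,
        src_start = tri_src$start, src_end = tri_src$end,
        chrom = tri_copies$chrom, start = tri_copies$start,
        end = tri_copies$end, divergence = 0.01,
        mode = "interchromosomal", in_reference = TRUE, in_donor = TRUE,
        expect_in_map = FALSE
      )
      # assembly artifacts: in the assembly, absent from the individual
      art <- bind_rows(lapply(1:2, function(j) {
        len <- c(12000, 8000)[j]
        src <- alloc$alloc(len)
        cpy <- alloc$alloc(len, not_chrom = src$chrom)
        tibble(
          event_id = paste0("artifact", j), src_chrom = src$chrom,
          src_start = src$start, src_end = src$end,
          chrom = cpy$chrom, start = cpy$start, end = cpy$end,
          divergence = c(0.01, 0.03)[j], mode = "interchromosomal",
          in_reference = TRUE, in_donor = FALSE, expect_in_map = FALSE
        )
      }))
      ev <- bind_rows(ev, fam, tri, art)
    }
    ev
  })

  sim <- plant_duplications(genome, events,
                            seed = derive_seed(seed, "duplications"))
  sim$truth$repeats <- reps$repeats
  reads <- simulate_reads(sim$donor, depth = depth / 2,
                          read_length = 36, error_rate = 0.005,
                          seed = derive_seed(seed, "reads"))
  centromeres <- setNames(as.double(chrom_lengths) / 2, names(chrom_lengths))

  out <- list(reference = sim$reference, donor = sim$donor,
              truth = sim$truth, repeats = reps$repeats, reads = reads,
              centromeres = centromeres, scale = scale, seed = seed,
              depth = depth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- list(
      genome = file.path(outdir, "reference.fa"),
      donor_hap1 = file.path(outdir, "donor_hap1.fa"),
      donor_hap2 = file.path(outdir, "donor_hap2.fa"),
      reads = file.path(outdir, "reads.fastq"),
      repeats = file.path(outdir, "repeats.bed"),
      truth = file.path(outdir, "truth.json"),
      truth_bed = file.path(outdir, "truth_sd.bed"),
      centromeres = file.path(outdir, "centromeres.tsv")
    )
    write_genome_fasta(sim$reference, p$genome)
    write_genome_fasta(sim$donor$hap1, p$donor_hap1)
    write_genome_fasta(sim$donor$hap2, p$donor_hap2)
    write_reads_fastq(reads, p$reads)
    write_bed(reps$repeats, p$repeats)
    write_truth_json(sim$truth, p$truth)
    write_bed(truth_intervals(sim$truth), p$truth_bed)
    readr::write_tsv(tibble(chrom = names(centromeres),
                            position = centromeres),
                     p$centromeres, progress = FALSE)
    out$paths <- p
  }
  out
}

# --------------------------------------------------------------------------
# full pipeline

resolve_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1) return(read_genome_fasta(x))
  stop_invalid("genome must be a FASTA path or a DNAStringSet")
}

resolve_reads <- function(x) {
  if (inherits(x, "read_set")) return(x)
  if (is.character(x) && length(x) == 1) return(read_reads_fastq(x))
  stop_invalid("reads must be a FASTQ path or a read_set")
}

resolve_intervals <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) return(read_bed(x))
  check_intervals(x)
}

resolve_centromeres <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) {
    tb <- readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
    return(setNames(tb$position, tb$chrom))
  }
  x
}

md5_of <- function(paths) {
  paths <- unlist(paths)
  if (is.null(paths) || length(paths) == 0) return(list())
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(list())
  sums <- tools::md5sum(paths)
  as.list(setNames(as.character(sums), basename(names(sums))))
}

run_stage <- function(stage, expr) {
  log_stage("stage ", stage, " started")
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
          class = "sdscape_stage_error", parent = e)
  })
}

#' Run the full SD pipeline
#'
#' Executes WGAC self-alignment, WSSD depth analysis, the 94% combination
#' rule, optional landmark enrichment and optional gene-content summaries,
#' writing every stage output plus a run manifest into `config$outdir`.
#'
#' @param config A `run_config` from [sd_config()].
#' @return List with the main results (`alignments`, `cleaned`, `wssd`,
#'   `profile`, `map`, `verification`, `enrichment`, `genes`) and the
#'   `manifest`.
#' @export
run_sd_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  genome <- run_stage("load", resolve_genome(config$genome))
  reads <- run_stage("load", resolve_reads(config$reads))
  repeats <- resolve_intervals(config$repeats)
  if (is.null(repeats)) {
    warn("no repeat annotation supplied: WGAC runs unmasked")
  }
  chrom_lengths <- chrom_lengths_of(genome)
  counts <- list()

  # WGAC
  initial <- run_stage("wgac", self_align(
    genome, repeats = repeats, k = config$k, min_len = config$min_len,
    min_identity = config$min_identity
  ))
  cleaned <- run_stage("wgac", filter_high_copy(
    initial, max_copies = config$max_copies, max_chroms = config$max_chroms
  ))
  counts$wgac_initial <- nrow(initial)
  counts$wgac_cleaned <- nrow(cleaned)
  readr::write_tsv(initial, file.path(outdir, "wgac_initial.tsv"),
                   progress = FALSE)
  readr::write_tsv(cleaned, file.path(outdir, "wgac_cleaned.tsv"),
                   progress = FALSE)

  # WSSD
  placements <- run_stage("wssd", place_reads(
    reads, genome, max_mismatches = config$max_mismatches
  ))
  profile <- run_stage("wssd", profile_depth(
    placements, genome, repeats = repeats, window = config$window,
    slide = config$slide,
    exclude = if (nrow(cleaned) > 0) {
      alignment_loci(cleaned)[, c("chrom", "start", "end")]
    } else NULL
  ))
  wssd <- run_stage("wssd", call_wssd_intervals(
    profile, z = config$z, min_len = config$wssd_min_len
  ))
  counts$reads <- length(reads$reads)
  counts$placements <- nrow(placements)
  counts$unmapped <- attr(placements, "unmapped")
  counts$wssd_intervals <- nrow(wssd)
  write_depth_bedgraph(profile, file.path(outdir, "wssd_depth.bedgraph"))
  write_bed(wssd, file.path(outdir, "wssd_intervals.bed"))

  # combine
  parts <- run_stage("combine", split_by_identity(cleaned, cut = config$cut))
  val <- run_stage("combine", validate_high_identity(
    parts$high, wssd, min_support = config$min_support
  ))
  map <- run_stage("combine", build_final_map(
    parts$low, val$validated, wssd, chrom_lengths
  ))
  verification <- suppressWarnings(verification_proportion(
    cleaned, wssd, min_len = config$wssd_min_len, cut = config$cut,
    min_support = config$min_support
  ))
  counts$high_identity <- nrow(parts$high)
  counts$validated <- nrow(val$validated)
  counts$artifactual <- nrow(val$artifactual)
  counts$sd_regions <- nrow(map$regions)
  write_bed(map$regions, file.path(outdir, "sd_map.bed"))
  jsonlite::write_json(
    c(map$summary[c("total_sd_length", "genome_length", "sd_content")],
      list(verification_proportion = verification,
           per_chromosome = map$summary$per_chromosome)),
    file.path(outdir, "sd_summary.json"), auto_unbox = TRUE, digits = NA
  )

  # enrichment (optional)
  enrichment <- NULL
  centromeres <- resolve_centromeres(config$centromeres)
  if (!is.null(centromeres) && nrow(map$regions) > 0) {
    enrichment <- run_stage("enrich", {
      lms <- build_landmarks(chrom_lengths, centromeres,
                             flank = config$flank,
                             short_chrom_flank = config$short_chrom_flank,
                             short_chroms = config$short_chroms)
      lapply(lms, function(lm) {
        empirical_enrichment(
          map$regions, lm, chrom_lengths, mode = "length",
          n_replicates = config$n_replicates,
          seed = derive_seed(config$seed, "enrich")
        )
      })
    })
    jsonlite::write_json(
      lapply(enrichment, function(e) as.list(tidy(e))),
      file.path(outdir, "enrichment.json"), auto_unbox = TRUE, digits = NA
    )
  }

  # gene content (optional)
  gene_tab <- NULL
  genes_in <- config$genes
  if (!is.null(genes_in)) {
    gene_tab <- run_stage("genes", {
      ann <- if (is.character(genes_in)) {
        readr::read_tsv(genes_in, show_col_types = FALSE, progress = FALSE)
      } else {
        as_tibble(genes_in)
      }
      gs <- genes_in_sd(ann, map$regions)
      assign_gene_cn(gs, wssd)
    })
    counts$genes_in_sd <- nrow(gene_tab)
    readr::write_tsv(gene_tab, file.path(outdir, "genes_in_sd.tsv"),
                     progress = FALSE)
    readr::write_tsv(bin_gene_cn(gene_tab),
                     file.path(outdir, "gene_cn_bins.tsv"), progress = FALSE)
  }

  # manifest
  input_paths <- Filter(function(x) is.character(x) && length(x) == 1,
                        config[c("genome", "reads", "repeats", "genes",
                                 "centromeres")])
  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("sdscape")),
    config = config_snapshot(config),
    inputs = md5_of(input_paths),
    counts = counts,
    outputs = md5_of(as.list(outputs)),
    wall_time = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("pipeline finished in ", round(manifest$wall_time, 1), " s")

  list(alignments = initial, cleaned = cleaned, placements_n = nrow(placements),
       profile = profile, wssd = wssd, map = map,
       verification = verification, enrichment = enrichment,
       genes = gene_tab, manifest = manifest, outdir = outdir)
}

# Config as stored in the manifest: parameters plus input basenames; the
# output directory is omitted so runs in different directories compare
# equal when their inputs and parameters match.
config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$outdir <- NULL
  for (f in c("genome", "reads", "repeats", "genes", "centromeres")) {
    snap[[f]] <- if (is.character(snap[[f]])) basename(snap[[f]]) else {
      if (is.null(snap[[f]])) NULL else paste0("<in-memory ", f, ">")
    }
  }
  snap
}
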