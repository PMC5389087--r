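# WGAC stage: whole-genome self-comparison. Repeat-masked, excised genome is
# self-aligned with a gap-free seed-merge-extend kernel; alignments >= 1 kb
# and >= 90% identity are reported as duplication evidence, then artifactual
# high-copy families are removed.

SEP_N <- 60 # separator Ns between concatenated chromosomes

concat_genome <- function(genome) {
  chars <- as.character(genome)
  lens <- nchar(chars)
  offs <- cumsum(c(0, head(lens + SEP_N, -1)))
  list(
    s = paste(chars, collapse = strrep("N", SEP_N)),
    offsets = tibble(chrom = names(chars), offset = offs, len = lens)
  )
}

global_to_local <- function(pos, offsets) {
  idx <- findInterval(pos, offsets$offset)
  tibble(chrom = offsets$chrom[idx],
         pos = unname(pos - offsets$offset[idx]))
}

#' Mask and excise known repeats
#'
#' Removes repeat bases from the genome before self-alignment so common
#' interspersed repeats do not seed spurious duplication alignments, and
#' returns the coordinate map needed to lift condensed positions back to
#' the original assembly exactly.
#'
#' @param genome `DNAStringSet`.
#' @param repeats Repeat interval tibble (`chrom`, `start`, `end`);
#'   overlapping records are merged with a warning.
#' @return List with `genome` (condensed `DNAStringSet`) and `map`
#'   (tibble of kept segments: `chrom`, `orig_start`, `orig_end`,
#'   `cond_start`).
#' @export
mask_repeats <- function(genome, repeats) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  repeats <- check_intervals(repeats, "repeats")
  chrom_lengths <- chrom_lengths_of(genome)
  if (nrow(repeats) > 0) {
    if (!all(repeats$chrom %in% names(chrom_lengths)) ||
        any(repeats$end > chrom_lengths[repeats$chrom]) ||
        any(repeats$start < 0)) {
      stop_invalid("repeat intervals fall outside the genome")
    }
    merged <- merge_intervals(repeats)
    if (nrow(merged) < nrow(distinct(repeats, .data$chrom, .data$start, .data$end))) {
      warn("overlapping repeat records merged before excision")
    }
    repeats <- merged
  }
  segs <- vector("list", length(chrom_lengths))
  out <- as.character(genome)
  for (i in seq_along(chrom_lengths)) {
    ch <- names(chrom_lengths)[i]
    keep <- setdiff_intervals(
      tibble(chrom = ch, start = 0, end = chrom_lengths[[i]]),
      repeats[repeats$chrom == ch, , drop = FALSE]
    )
    if (nrow(keep) == 0) {
      out[[ch]] <- ""
      segs[[i]] <- tibble(chrom = character(), orig_start = double(),
                          orig_end = double(), cond_start = double())
      next
    }
    pieces <- substring(out[[ch]], keep$start + 1, keep$end)
    out[[ch]] <- paste(pieces, collapse = "")
    w <- keep$end - keep$start
    segs[[i]] <- tibble(chrom = ch, orig_start = keep$start,
                        orig_end = keep$end,
                        cond_start = cumsum(c(0, head(w, -1))))
  }
  out <- out[nchar(out) > 0]
  list(genome = Biostrings::DNAStringSet(out), map = bind_rows(segs))
}

#' Lift condensed coordinates back to the original assembly
#'
#' `lift_interval()` maps a condensed-space interval to original
#' coordinates; an interval spanning an excision junction expands across
#' the excised repeat (the repeat bases are re-included in the reported
#' locus, as in repeat-reinsertion after masked alignment).
#' `lift_position()` maps a single original-space position into condensed
#' space and errors if the position lies inside an excised repeat.
#'
#' @param map Segment map from [mask_repeats()].
#' @param chrom,start,end,pos Coordinates (vectors allowed).
#' @return `lift_interval()`: tibble `chrom`, `start`, `end`;
#'   `lift_position()`: numeric condensed positions.
#' @export
lift_interval <- function(map, chrom, start, end) {
  n <- length(chrom)
  o_start <- o_end <- numeric(n)
  for (i in seq_len(n)) {
    m <- map[map$chrom == chrom[i], , drop = FALSE]
    w <- m$orig_end - m$orig_start
    j1 <- findInterval(start[i], m$cond_start)
    j2 <- findInterval(end[i] - 1, m$cond_start)
    if (j1 < 1 || j2 < 1 || start[i] >= m$cond_start[j1] + w[j1] ||
        end[i] - 1 >= m$cond_start[j2] + w[j2]) {
      stop_invalid("condensed coordinate outside the kept segments")
    }
    o_start[i] <- m$orig_start[j1] + (start[i] - m$cond_start[j1])
    o_end[i] <- m$orig_start[j2] + (end[i] - 1 - m$cond_start[j2]) + 1
  }
  tibble(chrom = chrom, start = o_start, end = o_end)
}

#' @rdname lift_interval
#' @export
lift_position <- function(map, chrom, pos) {
  n <- length(pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m <- map[map$chrom == chrom[i], , drop = FALSE]
    j <- findInterval(pos[i], m$orig_start)
    if (j < 1 || pos[i] >= m$orig_end[j]) {
      stop_invalid(paste0("position ", pos[i], " on ", chrom[i],
                          " lies inside an excised repeat"))
    }
    out[i] <- m$cond_start[j] + (pos[i] - m$orig_start[j])
  }
  out
}

#' Whole-genome self-alignment
#'
#' Detects pairwise duplication alignments by comparing the (optionally
#' repeat-excised) assembly against itself: shared exact k-mer seeds are
#' merged along diagonals, extended gap-free with an X-drop rule, and
#' trimmed to the maximal segment whose running identity stays at or above
#' `min_identity`. Both orientations are searched; reported pairs are
#' canonically ordered (locus A lexicographically before locus B),
#' deduplicated, and lifted back to original coordinates.
#'
#' @param genome `DNAStringSet`.
#' @param repeats Optional repeat BED tibble; when supplied, repeats are
#'   excised before alignment via [mask_repeats()].
#' @param k Seed length, 12--20 (default 14).
#' @param min_len Minimum aligned length in bp (default 1000).
#' @param min_identity Minimum identity in \[0, 1\] (default 0.90).
#' @param xdrop X-drop threshold for the gap-free extension (default 20).
#' @param mismatch_penalty Extension mismatch penalty (match scores +1).
#' @param max_gap Maximum gap between same-diagonal seeds merged into one
#'   candidate (default 100 bp).
#' @param max_occ Seeds occurring more often than this are skipped.
#' @return Alignment tibble: `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `strand`, `aligned_length`, `identity` (4
#'   decimals), `stage = "initial"`.
#' @export
self_align <- function(genome, repeats = NULL, k = 14, min_len = 1000,
                       min_identity = 0.90, xdrop = 20, mismatch_penalty = 3,
                       max_gap = 100, max_occ = 200) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (k < 12 || k > 20) stop_invalid("seed length k must lie in [12, 20]")
  if (any(Biostrings::width(genome) < k)) {
    stop_invalid("genome contains a sequence shorter than the seed length k")
  }
  map <- NULL
  gen <- genome
  if (!is.null(repeats) && nrow(check_intervals(repeats)) > 0) {
    masked <- mask_repeats(genome, repeats)
    gen <- masked$genome
    map <- masked$map
  }
  cc <- concat_genome(gen)
  raw <- as_tibble(cpp_self_align(cc$s, as.integer(k), as.integer(min_len),
                                  min_identity, xdrop, mismatch_penalty,
                                  as.integer(max_gap), as.integer(max_occ)))
  if (nrow(raw) == 0) {
    return(empty_alignments("initial"))
  }
  la <- global_to_local(raw$a_start, cc$offsets)
  lb <- global_to_local(raw$b_start, cc$offsets)
  aln <- tibble(
    chrom_a = la$chrom, start_a = la$pos, end_a = la$pos + raw$length,
    chrom_b = lb$chrom, start_b = lb$pos, end_b = lb$pos + raw$length,
    strand = if_else(raw$strand == 1, "-", "+"),
    aligned_length = raw$length,
    identity = round(raw$matches / raw$length, 4)
  )
  if (!is.null(map)) {
    A <- lift_interval(map, aln$chrom_a, aln$start_a, aln$end_a)
    B <- lift_interval(map, aln$chrom_b, aln$start_b, aln$end_b)
    aln$start_a <- A$start; aln$end_a <- A$end
    aln$start_b <- B$start; aln$end_b <- B$end
  }
  canonicalize_alignments(aln, stage = "initial")
}

empty_alignments <- function(stage) {
  tibble(
    chrom_a = character(), start_a = double(), end_a = double(),
    chrom_b = character(), start_b = double(), end_b = double(),
    strand = character(), aligned_length = double(), identity = double(),
    stage = character()
  )
}

canonicalize_alignments <- function(aln, stage) {
  swap <- (aln$chrom_b < aln$chrom_a) |
    (aln$chrom_b == aln$chrom_a & aln$start_b < aln$start_a) |
    (aln$chrom_b == aln$chrom_a & aln$start_b == aln$start_a &
       aln$end_b < aln$end_a)
  sw <- function(x, y) list(if_else(swap, y, x), if_else(swap, x, y))
  ca <- sw(aln$chrom_a, aln$chrom_b)
  sa <- sw(aln$start_a, aln$start_b)
  ea <- sw(aln$end_a, aln$end_b)
  aln$chrom_a <- ca[[1]]; aln$chrom_b <- ca[[2]]
  aln$start_a <- sa[[1]]; aln$start_b <- sa[[2]]
  aln$end_a <- ea[[1]]; aln$end_b <- ea[[2]]
  aln <- aln[!(aln$chrom_a == aln$chrom_b & aln$start_a == aln$start_b &
                 aln$end_a == aln$end_b), , drop = FALSE]
  aln |>
    distinct(.data$chrom_a, .data$start_a, .data$end_a, .data$chrom_b,
             .data$start_b, .data$end_b, .data$strand, .keep_all = TRUE) |>
    arrange(.data$chrom_a, .data$start_a, .data$chrom_b, .data$start_b) |>
    mutate(stage = stage)
}

# Long format: one row per alignment side.
alignment_loci <- function(aln) {
  bind_rows(
    tibble(aln_id = seq_len(nrow(aln)), side = "a", chrom = aln$chrom_a,
           start = aln$start_a, end = aln$end_a),
    tibble(aln_id = seq_len(nrow(aln)), side = "b", chrom = aln$chrom_b,
           start = aln$start_b, end = aln$end_b)
  )
}

# Map each locus to the merged duplicon block covering it.
loci_to_blocks <- function(loci) {
  blocks <- merge_intervals(loci)
  blocks$block <- seq_len(nrow(blocks))
  key <- integer(nrow(loci))
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    bi <- which(blocks$chrom == ch)
    j <- findInterval(loci$start[li], blocks$start[bi])
    key[li] <- blocks$block[bi][j]
  }
  list(blocks = blocks, block_of = key)
}

#' Remove artifactual high-copy duplicon families
#'
#' Duplicated loci are clustered into duplicon families: loci merged by
#' single-linkage interval overlap form blocks, and blocks linked by any
#' pairwise alignment belong to one family. Families with `max_copies` or
#' more member blocks, or with members on `max_chroms` or more distinct
#' chromosomes, are removed together with all their alignments; the
#' survivors pass through unchanged with `stage = "cleaned"`.
#'
#' @param alignments Alignment tibble from [self_align()].
#' @param max_copies Copy-count threshold (default 50: families with 50 or
#'   more copies are dropped).
#' @param max_chroms Chromosome-count threshold (default 3: families
#'   present on 3 or more chromosomes are dropped).
#' @return Cleaned alignment tibble.
#' @export
filter_high_copy <- function(alignments, max_copies = 50, max_chroms = 3) {
  if (nrow(alignments) == 0) {
    return(mutate(alignments, stage = character(0)))
  }
  loci <- alignment_loci(alignments)
  lb <- loci_to_blocks(loci)
  nb <- nrow(lb$blocks)

  # union-find over blocks; alignments are the edges
  parent <- seq_len(nb)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  a_block <- lb$block_of[loci$side == "a"][order(loci$aln_id[loci$side == "a"])]
  b_block <- lb$block_of[loci$side == "b"][order(loci$aln_id[loci$side == "b"])]
  for (i in seq_along(a_block)) {
    ra <- find(a_block[i]); rb <- find(b_block[i])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_len(nb), find, integer(1))
  fam_size <- table(root)
  fam_chroms <- tapply(lb$blocks$chrom, root, function(x) length(unique(x)))
  bad_fams <- names(fam_size)[
    fam_size >= max_copies | fam_chroms[names(fam_size)] >= max_chroms
  ]
  bad_aln <- root[a_block] %in% as.integer(bad_fams) |
    root[b_block] %in% as.integer(bad_fams)
  mutate(alignments[!bad_aln, , drop = FALSE], stage = "cleaned")
}

#' Identity histogram of pairwise alignments
#'
#' Counts alignments per 1-percentage-point identity bin over 90--100%.
#' The bin labelled `b` covers identities in `[b, b + 1)` percent; the
#' last bin (99) is closed at 100.
#'
#' @param alignments Alignment tibble.
#' @return Tibble `bin` (90--99), `count`; counts sum to `nrow(alignments)`.
#' @export
identity_histogram <- function(alignments) {
  bins <- 90:99
  if (nrow(alignments) == 0) {
    return(tibble(bin = bins, count = rep(0L, length(bins))))
  }
  b <- pmin(floor(alignments$identity * 100), 99)
  tb <- table(factor(b, levels = bins))
  tibble(bin = bins, count = as.integer(tb))
}

#' Plot the alignment identity distribution
#'
#' @param alignments Alignment tibble.
#' @return A ggplot.
#' @export
plot_identity_histogram <- function(alignments) {
  h <- identity_histogram(alignments)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "alignment identity (%)", y = "pairwise alignments") +
    ggplot2::theme_minimal()
}
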