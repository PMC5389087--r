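# Combination stage: the final SD map is WGAC-derived, with the WSSD depth
# evidence used to remove artifactual high-identity duplications -- the
# <94% alignments pass directly, the >=94% alignments must be supported by
# read depth.

#' Split cleaned alignments at the identity cut
#'
#' @param alignments Cleaned alignment tibble.
#' @param cut Identity boundary (default 0.94); alignments at or above the
#'   cut go to the high set (the boundary is inclusive on the filtered
#'   side).
#' @return List with `low` (identity < cut) and `high` (identity >= cut).
#' @export
split_by_identity <- function(alignments, cut = 0.94) {
  list(
    low = alignments[alignments$identity < cut, , drop = FALSE],
    high = alignments[alignments$identity >= cut, , drop = FALSE]
  )
}

# Coverage fraction of each alignment side by the merged WSSD intervals.
locus_support <- function(aln, wssd) {
  loci <- alignment_loci(aln)
  frac <- overlap_bases_per_row(loci, wssd) / (loci$end - loci$start)
  tibble(aln_id = loci$aln_id, side = loci$side, support = frac)
}

#' Validate high-identity alignments against read depth
#'
#' A duplicated locus of a high-identity alignment is kept when at least
#' `min_support` of its length is covered by WSSD intervals; an alignment
#' survives if either of its loci is kept. Alignments failing on both
#' sides are artifactual duplications (assembly errors without depth
#' support).
#'
#' @param high High-identity alignment tibble (from [split_by_identity()]).
#' @param wssd WSSD interval tibble.
#' @param min_support Minimum covered fraction per locus (default 0.5).
#' @return List with `validated` and `artifactual` alignment tibbles.
#' @export
validate_high_identity <- function(high, wssd, min_support = 0.5) {
  if (nrow(high) == 0) {
    return(list(validated = high, artifactual = high))
  }
  sup <- locus_support(high, wssd)
  keep_side <- sup$support >= min_support
  keep <- tapply(keep_side, sup$aln_id, any)
  keep <- as.logical(keep[as.character(seq_len(nrow(high)))])
  list(
    validated = high[keep, , drop = FALSE],
    artifactual = high[!keep, , drop = FALSE]
  )
}

#' Build the final segmental-duplication map
#'
#' Merges the duplicated loci of the low-identity and the depth-validated
#' high-identity alignments into disjoint SD regions, annotates each region
#' with its support class, the highest contributing alignment identity and
#' (where available) the WSSD copy number, and computes the SD content
#' summary. WSSD intervals without any WGAC evidence are reported in a
#' separate `wssd_only` track and are not counted in the map.
#'
#' @param low Low-identity alignment tibble.
#' @param validated Validated high-identity alignment tibble.
#' @param wssd WSSD interval tibble (with `copy_number`).
#' @param chrom_lengths Named vector of chromosome lengths (for the
#'   summary), or a `DNAStringSet`.
#' @return An `sd_map`: `regions`, `wssd_only`, `summary`.
#' @export
build_final_map <- function(low, validated, wssd, chrom_lengths) {
  chrom_lengths <- chrom_lengths_of(chrom_lengths)
  wssd <- check_intervals(wssd, "wssd")
  all_aln <- bind_rows(low, validated)
  low_loci <- if (nrow(low) > 0) {
    alignment_loci(low)[, c("chrom", "start", "end")]
  } else NULL
  val_loci <- if (nrow(validated) > 0) {
    alignment_loci(validated)[, c("chrom", "start", "end")]
  } else NULL
  regions <- merge_intervals(bind_rows(low_loci, val_loci))

  if (nrow(regions) > 0) {
    from_low <- overlaps_any(regions, low_loci %||%
                               tibble(chrom = character(), start = double(),
                                      end = double()))
    from_val <- overlaps_any(regions, val_loci %||%
                               tibble(chrom = character(), start = double(),
                                      end = double()))
    regions$support <- dplyr::case_when(
      from_low & from_val ~ "wgac_low+wgac_high_validated",
      from_val ~ "wgac_high_validated",
      TRUE ~ "wgac_low"
    )
    regions$max_identity <- region_max_identity(regions, all_aln)
    regions$copy_number <- region_copy_number(regions, wssd)
  } else {
    regions <- tibble(chrom = character(), start = double(), end = double(),
                      support = character(), max_identity = double(),
                      copy_number = double())
  }

  wssd_only <- if (nrow(wssd) > 0) {
    wssd[!overlaps_any(wssd, regions), , drop = FALSE]
  } else {
    wssd
  }

  total <- if (nrow(regions) > 0) sum(regions$end - regions$start) else 0
  per_chrom <- tibble(chrom = names(chrom_lengths),
                      chrom_length = as.double(chrom_lengths)) |>
    left_join(
      if (nrow(regions) > 0) {
        regions |> group_by(.data$chrom) |>
          summarise(sd_length = sum(.data$end - .data$start))
      } else {
        tibble(chrom = character(), sd_length = double())
      },
      by = "chrom"
    ) |>
    mutate(sd_length = dplyr::coalesce(.data$sd_length, 0))
  structure(
    list(
      regions = regions,
      wssd_only = wssd_only,
      summary = list(
        total_sd_length = total,
        genome_length = sum(chrom_lengths),
        sd_content = total / sum(chrom_lengths),
        per_chromosome = per_chrom
      )
    ),
    class = "sd_map"
  )
}

region_max_identity <- function(regions, aln) {
  if (nrow(aln) == 0) return(rep(NA_real_, nrow(regions)))
  loci <- alignment_loci(aln)
  loci$identity <- aln$identity[loci$aln_id]
  out <- rep(NA_real_, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- loci$chrom == regions$chrom[i] &
      loci$start < regions$end[i] & loci$end > regions$start[i]
    if (any(hit)) out[i] <- max(loci$identity[hit])
  }
  out
}

region_copy_number <- function(regions, wssd) {
  out <- rep(NA_real_, nrow(regions))
  if (nrow(wssd) == 0 || !"copy_number" %in% names(wssd)) return(out)
  for (i in seq_len(nrow(regions))) {
    ov <- pmin(wssd$end, regions$end[i]) - pmax(wssd$start, regions$start[i])
    ov[wssd$chrom != regions$chrom[i]] <- 0
    j <- which.max(ov)
    if (length(j) == 1 && ov[j] > 0) out[i] <- wssd$copy_number[j]
  }
  out
}

#' @export
print.sd_map <- function(x, ...) {
  s <- x$summary
  cat("<sd_map> ", nrow(x$regions), " regions, ",
      format(s$total_sd_length, big.mark = ","), " bp (",
      sprintf("%.2f%%", 100 * s$sd_content), " of ",
      format(s$genome_length, big.mark = ","), " bp); ",
      nrow(x$wssd_only), " WSSD-only intervals in the side track\n", sep = "")
  invisible(x)
}

#' @export
tidy.sd_map <- function(x, ...) x$regions

#' @export
glance.sd_map <- function(x, ...) {
  tibble(
    n_regions = nrow(x$regions),
    total_sd_length = x$summary$total_sd_length,
    genome_length = x$summary$genome_length,
    sd_content = x$summary$sd_content,
    n_wssd_only = nrow(x$wssd_only)
  )
}

#' Proportion of long high-identity WGAC loci verified by WSSD
#'
#' Collects the duplicated loci of alignments at or above the identity
#' cut, merges them, keeps merged loci longer than `min_len` (strictly),
#' and reports the fraction of their total length belonging to loci whose
#' WSSD coverage reaches `min_support`. A low proportion flags an assembly
#' whose high-identity duplications lack read-depth support.
#'
#' @param alignments Cleaned alignment tibble.
#' @param wssd WSSD interval tibble.
#' @param min_len Length floor in bp, exclusive (default 10,000).
#' @param cut Identity cut (default 0.94).
#' @param min_support Covered-fraction threshold per locus (default 0.5).
#' @return Proportion in \[0, 1\], or `NA` (with a warning) when no locus
#'   qualifies.
#' @export
verification_proportion <- function(alignments, wssd, min_len = 10000,
                                    cut = 0.94, min_support = 0.5) {
  high <- alignments[alignments$identity >= cut, , drop = FALSE]
  if (nrow(high) == 0) {
    warn("no alignments at or above the identity cut: proportion undefined")
    return(NA_real_)
  }
  loci <- merge_intervals(alignment_loci(high)[, c("chrom", "start", "end")])
  loci <- loci[loci$end - loci$start > min_len, , drop = FALSE]
  if (nrow(loci) == 0) {
    warn("no merged loci above the length floor: proportion undefined")
    return(NA_real_)
  }
  frac <- overlap_bases_per_row(loci, wssd) / (loci$end - loci$start)
  sum((loci$end - loci$start)[frac >= min_support]) /
    sum(loci$end - loci$start)
}
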