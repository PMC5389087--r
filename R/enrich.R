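# Permutation enrichment: are SDs (or gene sets) associated with genomic
# landmarks? Query regions are re-placed uniformly and without mutual
# overlap many times to build an empirical null for the overlap statistic.

#' Build pericentromeric and subtelomeric landmark sets
#'
#' Subtelomeric regions are the first and last `flank` bp of every
#' chromosome; pericentromeric regions extend `flank` bp on each side of
#' the centromere position, clipped to the chromosome. Designated short
#' chromosomes use `short_chrom_flank` instead. Colliding regions are
#' merged.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param centromeres Named vector of centromere positions (bp); a
#'   chromosome without one contributes only subtelomeric regions (with a
#'   warning).
#' @param flank Flank width in bp (default 2 Mb).
#' @param short_chrom_flank Flank for short chromosomes (default 300 kb).
#' @param short_chroms Character vector of chromosome names that take the
#'   short flank.
#' @return List of two merged interval tibbles: `subtelomeric`,
#'   `pericentromeric`.
#' @export
build_landmarks <- function(chrom_lengths, centromeres = NULL, flank = 2e6,
                            short_chrom_flank = 3e5,
                            short_chroms = character()) {
  if (any(flank <= 0) || any(short_chrom_flank <= 0)) {
    stop_invalid("flanks must be positive")
  }
  chroms <- names(chrom_lengths)
  fl <- ifelse(chroms %in% short_chroms, short_chrom_flank, flank)
  sub <- bind_rows(
    tibble(chrom = chroms, start = 0,
           end = pmin(fl, as.double(chrom_lengths))),
    tibble(chrom = chroms,
           start = pmax(0, as.double(chrom_lengths) - fl),
           end = as.double(chrom_lengths))
  )
  peri <- NULL
  if (!is.null(centromeres) && length(centromeres) > 0) {
    missing_cen <- setdiff(chroms, names(centromeres))
    if (length(missing_cen) > 0) {
      warn(paste("no centromere position for:",
                 paste(missing_cen, collapse = ", "),
                 "- these contribute only subtelomeric regions"))
    }
    have <- intersect(chroms, names(centromeres))
    cen <- centromeres[have]
    if (any(cen < 0 | cen > chrom_lengths[have])) {
      stop_invalid("centromere positions must lie within their chromosomes")
    }
    flh <- fl[match(have, chroms)]
    peri <- tibble(
      chrom = have,
      start = pmax(0, as.double(cen) - flh),
      end = pmin(as.double(chrom_lengths[have]), as.double(cen) + flh)
    )
  } else {
    warn("no centromere positions supplied: pericentromeric set is empty")
  }
  list(
    subtelomeric = merge_intervals(sub),
    pericentromeric = if (is.null(peri)) {
      tibble(chrom = character(), start = double(), end = double())
    } else {
      merge_intervals(peri)
    }
  )
}

check_shuffle_space <- function(regions, chrom_lengths) {
  if (sum(regions$end - regions$start) >= sum(chrom_lengths)) {
    stop_placement("regions occupy the whole genome: placement impossible")
  }
}

#' Randomly re-place regions without overlap
#'
#' Each region keeps its length and is assigned a uniform position: the
#' chromosome is drawn proportional to its length, the start uniformly
#' over the feasible range, and placements colliding with already-placed
#' regions are rejected and retried.
#'
#' @param regions Interval tibble; lengths are preserved.
#' @param chrom_lengths Named vector of chromosome lengths defining the
#'   placement space.
#' @param seed Optional integer seed for reproducibility.
#' @param max_tries Attempts per region before failing (default 1000).
#' @return Tibble of placed intervals (same lengths, new positions).
#' @export
shuffle_regions <- function(regions, chrom_lengths, seed = NULL,
                            max_tries = 1000) {
  regions <- check_intervals(regions)
  check_shuffle_space(regions, chrom_lengths)
  pl <- with_seed(seed, {
    tryCatch(
      cpp_place_regions(regions$end - regions$start,
                        as.double(chrom_lengths), as.integer(max_tries)),
      error = function(e) stop_placement(conditionMessage(e))
    )
  })
  tibble(chrom = names(chrom_lengths)[pl$chrom], start = pl$start,
         end = pl$end)
}

#' Overlap statistic between regions and landmarks
#'
#' @param regions,landmarks Interval tibbles; both are merged before
#'   counting.
#' @param mode `"count"` (landmark intervals overlapped by at least 1 bp)
#'   or `"length"` (total overlapping bases).
#' @return A single number.
#' @export
overlap_statistic <- function(regions, landmarks, mode = c("count", "length")) {
  mode <- match.arg(mode)
  regions <- merge_intervals(regions)
  landmarks <- merge_intervals(landmarks)
  if (mode == "length") {
    return(intersect_length(regions, landmarks))
  }
  sum(overlaps_any(landmarks, regions))
}

new_sd_enrichment <- function(mode, observed, null, n_replicates, seed) {
  null_mean <- mean(null)
  structure(
    list(
      statistic_mode = mode,
      observed = observed,
      null = null,
      null_mean = null_mean,
      null_sd = stats::sd(null),
      n_replicates = n_replicates,
      fold = if (null_mean > 0) observed / null_mean else NA_real_,
      empirical_p = (1 + sum(null >= observed)) / (1 + n_replicates),
      seed = seed
    ),
    class = "sd_enrichment"
  )
}

#' Permutation enrichment of regions in landmarks
#'
#' Computes the observed overlap statistic, then re-places the regions
#' `n_replicates` times (uniformly, mutually non-overlapping) to build the
#' empirical null. Fold enrichment is observed over null mean; the
#' empirical p-value uses the add-one convention
#' `(1 + #[null >= observed]) / (1 + n_replicates)`, an upper-tail
#' (enrichment) test.
#'
#' @param regions Query intervals (e.g. the SD map); merged before testing.
#' @param landmarks Landmark intervals (e.g. CNVRs); merged before testing.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param mode `"count"` or `"length"`.
#' @param n_replicates Number of permutations (default 10,000; at least
#'   100).
#' @param seed Integer seed (stored in the result).
#' @param max_tries Placement attempts per region per replicate.
#' @return An `sd_enrichment` object.
#' @export
empirical_enrichment <- function(regions, landmarks, chrom_lengths,
                                 mode = c("count", "length"),
                                 n_replicates = 10000, seed = 1,
                                 max_tries = 1000) {
  mode <- match.arg(mode)
  if (n_replicates < 100) stop_invalid("n_replicates must be at least 100")
  regions <- merge_intervals(regions)
  landmarks <- merge_intervals(landmarks)
  if (nrow(regions) == 0) stop_undefined("no query regions to test")
  if (nrow(landmarks) == 0) stop_undefined("no landmarks to test against")
  observed <- overlap_statistic(regions, landmarks, mode)
  null <- null_overlap_stats(regions, landmarks, chrom_lengths,
                             mode_int = as.integer(mode == "length"),
                             n_replicates, seed, max_tries)
  new_sd_enrichment(mode, observed, null, n_replicates, seed)
}

null_overlap_stats <- function(regions, landmarks, chrom_lengths, mode_int,
                               n_replicates, seed, max_tries) {
  check_shuffle_space(regions, chrom_lengths)
  chroms <- names(chrom_lengths)
  if (!all(landmarks$chrom %in% chroms) || !all(regions$chrom %in% chroms)) {
    stop_invalid("interval chromosomes missing from chrom_lengths")
  }
  lm <- arrange(
    mutate(landmarks, ci = match(.data$chrom, chroms)),
    .data$ci, .data$start
  )
  lm_offset <- c(0L, cumsum(tabulate(lm$ci, nbins = length(chroms))))
  with_seed(seed, {
    tryCatch(
      cpp_null_stats(
        regions$end - regions$start, as.double(chrom_lengths),
        as.integer(lm_offset), lm$start, lm$end,
        as.integer(mode_int), as.integer(n_replicates), as.integer(max_tries)
      ),
      error = function(e) stop_placement(conditionMessage(e))
    )
  })
}

#' Gene-family enrichment in the SD map
#'
#' Same permutation machinery with the SD map as the landmark set and the
#' family's gene intervals as the re-placed queries, reported for either
#' statistic (total length of family genes overlapping SDs, or their
#' number).
#'
#' @param sd_regions SD map intervals.
#' @param family_genes Gene intervals of the family under test (an empty
#'   set is an undefined-result error).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @inheritParams empirical_enrichment
#' @return An `sd_enrichment` object.
#' @export
gene_family_enrichment <- function(sd_regions, family_genes, chrom_lengths,
                                   mode = c("count", "length"),
                                   n_replicates = 10000, seed = 1,
                                   max_tries = 1000) {
  mode <- match.arg(mode)
  if (n_replicates < 100) stop_invalid("n_replicates must be at least 100")
  family_genes <- check_intervals(family_genes, "family_genes")
  if (nrow(family_genes) == 0) {
    stop_undefined("empty gene family: enrichment undefined")
  }
  sd_regions <- merge_intervals(sd_regions)
  if (nrow(sd_regions) == 0) stop_undefined("empty SD map")
  # gene intervals are re-placed each replicate; count mode counts how many
  # of the (placed) genes touch the SD map, length mode their overlap bases
  if (mode == "count") {
    observed <- sum(overlaps_any(family_genes, sd_regions))
    null <- null_overlap_stats(family_genes, sd_regions, chrom_lengths,
                               mode_int = 2L, n_replicates, seed, max_tries)
    return(new_sd_enrichment("count", observed, null, n_replicates, seed))
  }
  observed <- intersect_length(family_genes, sd_regions)
  null <- null_overlap_stats(merge_intervals(family_genes), sd_regions,
                             chrom_lengths, mode_int = 1L, n_replicates,
                             seed, max_tries)
  new_sd_enrichment("length", observed, null, n_replicates, seed)
}

#' @export
print.sd_enrichment <- function(x, ...) {
  cat("<sd_enrichment> mode=", x$statistic_mode,
      " observed=", signif(x$observed, 6),
      " null=", signif(x$null_mean, 6), "+/-", signif(x$null_sd, 4),
      " fold=", signif(x$fold, 4),
      " p=", signif(x$empirical_p, 4),
      " (", x$n_replicates, " replicates, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.sd_enrichment <- function(x, ...) {
  tibble(
    statistic_mode = x$statistic_mode, observed = x$observed,
    null_mean = x$null_mean, null_sd = x$null_sd, fold = x$fold,
    empirical_p = x$empirical_p, n_replicates = x$n_replicates,
    seed = x$seed
  )
}

#' @export
glance.sd_enrichment <- function(x, ...) tidy(x)

#' @export
autoplot.sd_enrichment <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null), ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(
      x = paste0("null overlap (", object$statistic_mode, ")"),
      y = "replicates",
      title = sprintf("fold = %.2f, empirical p = %.2g",
                      object$fold, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}
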