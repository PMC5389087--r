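# WSSD stage: duplications detected as excess mapped read depth, with
# absolute copy-number estimation against a calibrated diploid background.

#' Map reads to the reference
#'
#' Places each read at every locus matching with at most `max_mismatches`
#' substitutions (both strands); a multi-mapped read's depth contribution
#' is split equally among its equal-best loci, a deterministic alternative
#' to random best-hit assignment. Reads with no qualifying locus are
#' dropped and counted.
#'
#' @param reads A `read_set` (or `DNAStringSet` of equal-length reads).
#' @param genome Reference `DNAStringSet`.
#' @param max_mismatches Maximum substitutions per placement (default 2;
#'   for 36 bp reads this matches the 94% identity regime of the
#'   high-identity WGAC filter).
#' @return Placement tibble: `read`, `chrom`, `start` (0-based), `strand`,
#'   `mismatches`, `weight`; attribute `unmapped` counts dropped reads, and
#'   `read_length` records the read length.
#' @export
place_reads <- function(reads, genome, max_mismatches = 2) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  sq <- if (inherits(reads, "read_set")) reads$reads else reads
  if (length(sq) == 0) {
    warn("empty read set: returning empty placements")
    out <- tibble(read = integer(), chrom = character(), start = double(),
                  strand = character(), mismatches = integer(),
                  weight = double())
    attr(out, "unmapped") <- 0L
    attr(out, "read_length") <- NA_integer_
    return(out)
  }
  rl <- unique(Biostrings::width(sq))
  if (length(rl) != 1) stop_invalid("all reads must have equal length")
  if (rl > min(Biostrings::width(genome))) {
    stop_invalid("read length exceeds the shortest chromosome")
  }
  cc <- concat_genome(genome)
  hits <- cpp_map_reads(cc$s, as.character(sq), as.integer(rl),
                        as.integer(max_mismatches))
  loc <- global_to_local(hits$pos, cc$offsets)
  out <- tibble(
    read = hits$read, chrom = loc$chrom, start = loc$pos,
    strand = if_else(hits$strand == 1, "-", "+"),
    mismatches = hits$mismatches, weight = hits$weight
  )
  attr(out, "unmapped") <- hits$unmapped
  attr(out, "read_length") <- rl
  out
}

#' Sliding-window read-depth profile
#'
#' Computes weighted per-base coverage from read placements, summarizes it
#' in sliding windows (depth = mapped read bases over non-repeat window
#' bases), and calibrates the diploid background as the 5%-per-tail trimmed
#' mean/SD of callable windows outside known duplication loci.
#'
#' @param placements Placement tibble from [place_reads()].
#' @param genome Reference `DNAStringSet` (or named length vector).
#' @param repeats Optional repeat interval tibble; repeat bases are
#'   excluded from window denominators, and windows with under 50%
#'   non-repeat bases are flagged uncallable.
#' @param window,slide Window geometry in bp (defaults 5000/1000).
#' @param exclude Optional interval tibble (typically WGAC duplication
#'   loci) removed from the background calibration.
#' @param read_length Read length (taken from `placements` when absent).
#' @return A `wssd_profile`: window tibble, background mean/SD, and the
#'   per-chromosome coverage needed for interval statistics.
#' @export
profile_depth <- function(placements, genome, repeats = NULL, window = 5000,
                          slide = 1000, exclude = NULL, read_length = NULL) {
  if (slide > window) stop_invalid("slide must not exceed window")
  chrom_lengths <- chrom_lengths_of(genome)
  read_length <- read_length %||% attr(placements, "read_length")
  if (is.null(read_length)) stop_invalid("read_length not supplied")
  repeats <- check_intervals(repeats, "repeats")
  exclude <- check_intervals(exclude, "exclude")

  cov <- list()
  masks <- list()
  windows <- vector("list", length(chrom_lengths))
  for (i in seq_along(chrom_lengths)) {
    ch <- names(chrom_lengths)[i]
    len <- chrom_lengths[[i]]
    pl <- placements[placements$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = pl$start + 1,
                           width = pmin(read_length, len - pl$start))
    cv <- IRanges::coverage(ir, weight = pl$weight, width = len)
    cov[[ch]] <- cv
    rep_ch <- repeats[repeats$chrom == ch, , drop = FALSE]
    nonrep <- rep(TRUE, len)
    if (nrow(rep_ch) > 0) {
      for (j in seq_len(nrow(rep_ch))) {
        nonrep[(rep_ch$start[j] + 1):rep_ch$end[j]] <- FALSE
      }
    }
    masks[[ch]] <- rep_ch
    if (len < window) {
      windows[[i]] <- NULL
      next
    }
    cvv <- as.numeric(cv)
    num <- cumsum(cvv * nonrep)
    den <- cumsum(as.numeric(nonrep))
    starts <- seq(0, len - window, by = slide)
    n2 <- num[starts + window] - c(0, num[starts[-1]])
    d2 <- den[starts + window] - c(0, den[starts[-1]])
    windows[[i]] <- tibble(
      chrom = ch, start = starts, end = starts + window,
      nonrep_bases = d2,
      depth = if_else(d2 > 0, n2 / d2, 0),
      callable = d2 >= window / 2
    )
  }
  win <- bind_rows(windows)
  if (nrow(win) == 0 || !any(win$callable)) {
    stop_calibration("no callable windows: cannot calibrate background depth")
  }
  bg_pool <- win[win$callable, , drop = FALSE]
  if (nrow(exclude) > 0) {
    bg_pool <- bg_pool[!overlaps_any(bg_pool, exclude), , drop = FALSE]
  }
  if (nrow(bg_pool) == 0) {
    stop_calibration("no callable background windows after exclusions")
  }
  x <- sort(bg_pool$depth)
  k <- floor(0.05 * length(x))
  trimmed <- x[(k + 1):(length(x) - k)]
  bg_mean <- mean(trimmed)
  bg_sd <- stats::sd(trimmed)
  if (!is.finite(bg_sd) || bg_sd <= 0) {
    bg_sd <- max(sqrt(bg_mean * read_length / window), 1e-6)
  }
  structure(
    list(windows = win, window = window, slide = slide,
         background_mean = bg_mean, background_sd = bg_sd,
         coverage = cov, repeats = repeats, chrom_lengths = chrom_lengths,
         read_length = read_length),
    class = "wssd_profile"
  )
}

#' @export
print.wssd_profile <- function(x, ...) {
  cat("<wssd_profile> ", nrow(x$windows), " windows (", x$window, "/",
      x$slide, " bp); background ", round(x$background_mean, 2), " +/- ",
      round(x$background_sd, 2), "\n", sep = "")
  invisible(x)
}

# Mean depth over non-repeat bases of an interval.
interval_mean_depth <- function(profile, chrom, start, end) {
  n <- length(chrom)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cv <- profile$coverage[[chrom[i]]]
    if (is.null(cv)) { out[i] <- NA_real_; next }
    s <- max(0, start[i]); e <- min(length(cv), end[i])
    v <- as.numeric(S4Vectors::window(cv, s + 1, e))
    keep <- rep(TRUE, e - s)
    rp <- profile$repeats[profile$repeats$chrom == chrom[i], , drop = FALSE]
    if (nrow(rp) > 0) {
      for (j in seq_len(nrow(rp))) {
        lo <- max(rp$start[j], s); hi <- min(rp$end[j], e)
        if (hi > lo) keep[(lo - s + 1):(hi - s)] <- FALSE
      }
    }
    out[i] <- if (any(keep)) mean(v[keep]) else NA_real_
  }
  out
}

#' Call duplication intervals from excess read depth
#'
#' Flags callable windows whose depth exceeds
#' `background_mean + z * background_sd`, merges overlapping and adjacent
#' flagged windows into candidates, trims each candidate to the span of
#' its elevated slide-length tiles (a full window overlapping an excess
#' region only partially still exceeds the window threshold, so untrimmed
#' candidates overstate the region by up to a window width on each side),
#' discards trimmed spans shorter than `min_len`, and reports each
#' interval's mean depth (over non-repeat bases) and absolute copy number
#' (`2 * mean_depth / background_mean`).
#'
#' @param profile A calibrated `wssd_profile`.
#' @param z Flagging threshold in background SD units (default 3).
#' @param min_len Minimum merged interval length (default 10,000 bp).
#' @return Tibble `chrom`, `start`, `end`, `mean_depth`, `copy_number`.
#' @export
call_wssd_intervals <- function(profile, z = 3, min_len = 10000) {
  stopifnot(inherits(profile, "wssd_profile"))
  thr <- profile$background_mean + z * profile$background_sd
  w <- profile$windows
  flagged <- w[w$callable & w$depth > thr, , drop = FALSE]
  if (nrow(flagged) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  mean_depth = double(), copy_number = double()))
  }
  iv <- merge_intervals(flagged)
  iv <- trim_to_elevated_tiles(iv, profile, z)
  iv <- iv[iv$end - iv$start >= min_len, , drop = FALSE]
  if (nrow(iv) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  mean_depth = double(), copy_number = double()))
  }
  iv$mean_depth <- interval_mean_depth(profile, iv$chrom, iv$start, iv$end)
  iv$copy_number <- round(2 * iv$mean_depth / profile$background_mean, 1)
  iv
}

# Trim each candidate interval to [first, last] elevated tile of length
# `slide`. The tile threshold rescales the window SD by sqrt(window/slide)
# (shorter summaries are noisier).
trim_to_elevated_tiles <- function(iv, profile, z) {
  tile <- profile$slide
  thr <- profile$background_mean +
    z * profile$background_sd * sqrt(profile$window / tile)
  keep <- logical(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    starts <- seq(iv$start[i], iv$end[i] - 1, by = tile)
    ends <- pmin(starts + tile, iv$end[i])
    d <- interval_mean_depth(profile, rep(iv$chrom[i], length(starts)),
                             starts, ends)
    hot <- which(!is.na(d) & d > thr)
    if (length(hot) == 0) next
    iv$start[i] <- starts[min(hot)]
    iv$end[i] <- ends[max(hot)]
    keep[i] <- TRUE
  }
  iv[keep, , drop = FALSE]
}

#' Absolute copy number of an interval
#'
#' Diploid-scaled estimate `2 * mean_depth / background_mean`, reported to
#' one decimal. Works for any interval, called or planted.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @param profile A calibrated `wssd_profile`.
#' @return `intervals` with `mean_depth` and `copy_number` columns added.
#' @export
estimate_copy_number <- function(intervals, profile) {
  if (!inherits(profile, "wssd_profile") ||
      !is.finite(profile$background_mean) || profile$background_mean <= 0) {
    stop_calibration("profile is not calibrated")
  }
  intervals <- check_intervals(intervals)
  intervals$mean_depth <- interval_mean_depth(
    profile, intervals$chrom, intervals$start, intervals$end
  )
  intervals$copy_number <- round(
    2 * intervals$mean_depth / profile$background_mean, 1
  )
  intervals
}

#' Write a window depth track as bedGraph
#'
#' @param profile A `wssd_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_bedgraph <- function(profile, path) {
  w <- profile$windows
  readr::write_tsv(
    tibble(chrom = w$chrom, start = w$start, end = w$end,
           value = round(w$depth, 4)),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' @export
tidy.wssd_profile <- function(x, ...) x$windows

#' @export
glance.wssd_profile <- function(x, ...) {
  tibble(
    n_windows = nrow(x$windows),
    n_callable = sum(x$windows$callable),
    window = x$window, slide = x$slide,
    background_mean = x$background_mean,
    background_sd = x$background_sd
  )
}

#' @export
autoplot.wssd_profile <- function(object, ...) {
  w <- object$windows
  thr <- object$background_mean + 3 * object$background_sd
  ggplot2::ggplot(w[w$callable, ],
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$background_mean,
                        colour = "grey40", linetype = 2) +
    ggplot2::geom_hline(yintercept = thr, colour = "firebrick",
                        linetype = 3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "window depth") +
    ggplot2::theme_minimal()
}
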