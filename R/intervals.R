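# Interval arithmetic on 0-based half-open tibbles (chrom, start, end).
# IRanges does the heavy lifting; these wrappers keep the tidy BED-style
# coordinate convention at the package surface.

check_intervals <- function(x, arg = "intervals") {
  if (is.null(x)) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  if (ncol(x) == 0 && nrow(x) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  if (!all(need %in% names(x))) {
    stop_invalid(paste0("`", arg, "` must have columns chrom, start, end"))
  }
  if (nrow(x) > 0 && any(x$end <= x$start)) {
    stop_invalid(paste0("`", arg, "` has records with end <= start"))
  }
  x
}

# tibble -> IRangesList keyed by chromosome (1-based closed internally)
as_irl <- function(x, chroms = NULL) {
  x <- check_intervals(x)
  chroms <- chroms %||% unique(x$chrom)
  by <- split(x, factor(x$chrom, levels = chroms))
  lapply(by, function(d) IRanges::IRanges(start = d$start + 1, end = d$end))
}

irl_to_tibble <- function(irl) {
  rows <- lapply(names(irl), function(ch) {
    ir <- irl[[ch]]
    if (length(ir) == 0) return(NULL)
    tibble(chrom = ch, start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Merge an interval set
#'
#' Collapses overlapping and book-ended intervals into disjoint intervals
#' (base-level union).
#'
#' @param x Tibble with `chrom`, `start`, `end` (0-based, half-open).
#' @return Tibble of disjoint merged intervals, sorted.
#' @export
#' @examples
#' merge_intervals(tibble::tibble(
#'   chrom = "chr1", start = c(0, 1500), end = c(2000, 4000)
#' ))
merge_intervals <- function(x) {
  x <- check_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  irl <- as_irl(x)
  irl_to_tibble(lapply(irl, IRanges::reduce))
}

#' Total bases shared by two interval sets
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @return Total number of bases in the intersection of the two unions.
#' @export
intersect_length <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(chroms) == 0) return(0)
  ia <- as_irl(a, chroms)
  ib <- as_irl(b, chroms)
  tot <- 0
  for (ch in chroms) {
    tot <- tot + sum(IRanges::width(IRanges::intersect(ia[[ch]], ib[[ch]])))
  }
  tot
}

# Per-row overlap (in bases) of intervals in `x` with the merged set `y`.
overlap_bases_per_row <- function(x, y) {
  x <- check_intervals(x)
  y <- merge_intervals(y)
  out <- numeric(nrow(x))
  if (nrow(x) == 0 || nrow(y) == 0) return(out)
  chroms <- unique(x$chrom)
  iy <- as_irl(y, chroms)
  for (ch in chroms) {
    idx <- which(x$chrom == ch)
    if (length(idx) == 0 || length(iy[[ch]]) == 0) next
    ix <- IRanges::IRanges(start = x$start[idx] + 1, end = x$end[idx])
    hits <- IRanges::findOverlaps(ix, iy[[ch]])
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(
      ix[S4Vectors::queryHits(hits)], iy[[ch]][S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    out[idx[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

# TRUE per row of `x` if it overlaps the merged set `y` by >= 1 base.
overlaps_any <- function(x, y) {
  overlap_bases_per_row(x, y) >= 1
}

# Subtract merged set `y` from merged set `x` (base-level difference).
setdiff_intervals <- function(x, y) {
  x <- merge_intervals(x)
  y <- merge_intervals(y)
  if (nrow(x) == 0 || nrow(y) == 0) return(x)
  chroms <- unique(x$chrom)
  ix <- as_irl(x, chroms)
  iy <- as_irl(y, chroms)
  irl_to_tibble(setNames(lapply(chroms, function(ch) {
    IRanges::setdiff(ix[[ch]], iy[[ch]])
  }), chroms))
}

interval_width_total <- function(x) {
  x <- merge_intervals(x)
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start)
}
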