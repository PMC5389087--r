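# Gene content of SD regions: intersection with annotation, per-gene copy
# numbers binned Table-3 style, and cross-species common-gene sets through
# an ortholog map.

CN_BREAKS <- c(-Inf, 1.5, 2.5, seq(10.5, 100.5, by = 10), Inf)
CN_LABELS <- c("<=1.5", "1.5-2.5", "2.5-10.5", "10.5-20.5", "20.5-30.5",
               "30.5-40.5", "40.5-50.5", "50.5-60.5", "60.5-70.5",
               "70.5-80.5", "80.5-90.5", "90.5-100.5", ">100.5")

#' Genes overlapping the SD map
#'
#' A gene is included when its overlap with the merged SD map reaches
#' `min_overlap` bases; each included gene carries its overlap fraction.
#' Malformed annotation rows (missing coordinates, `end <= start`) are
#' skipped and counted in the `skipped` attribute.
#'
#' @param genes Gene annotation tibble: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), optional `strand`.
#' @param sd_regions SD interval tibble (merged internally).
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return Tibble of included genes with `overlap_bases` and
#'   `overlap_fraction`.
#' @export
genes_in_sd <- function(genes, sd_regions, min_overlap = 1) {
  genes <- as_tibble(genes)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(genes))) {
    stop_invalid("gene annotation needs columns gene_id, chrom, start, end")
  }
  ok <- !is.na(genes$chrom) & !is.na(genes$start) & !is.na(genes$end) &
    genes$end > genes$start
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    inform(paste("skipped", n_skip, "malformed annotation rows"))
  }
  genes <- genes[ok, , drop = FALSE]
  sd <- merge_intervals(sd_regions)
  ov <- overlap_bases_per_row(genes, sd)
  out <- genes[ov >= min_overlap, , drop = FALSE]
  out$overlap_bases <- ov[ov >= min_overlap]
  out$overlap_fraction <- out$overlap_bases / (out$end - out$start)
  attr(out, "skipped") <- n_skip
  out
}

#' Assign per-gene copy numbers from WSSD intervals
#'
#' Each gene takes the copy number of the WSSD interval with the largest
#' overlap over its span; genes touching no WSSD interval get `NA`
#' (reported as the Null bin).
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param wssd WSSD interval tibble with a `copy_number` column.
#' @return `genes` with a `copy_number` column.
#' @export
assign_gene_cn <- function(genes, wssd) {
  genes <- as_tibble(genes)
  genes$copy_number <- region_copy_number(genes, check_intervals(wssd, "wssd"))
  genes
}

#' Bin gene copy numbers (Table-3 style)
#'
#' Bins are right-closed with edges at 1.5, 2.5, 10.5, 20.5, ..., 100.5,
#' plus a Null bin for genes without an estimate. The average copy number
#' is taken over non-null genes, to one decimal.
#'
#' @param genes Gene tibble with a `copy_number` column (possibly `NA`).
#' @return A `cn_bin_table` tibble (`bin`, `count`) whose counts sum to
#'   `nrow(genes)`; attributes `ave_cn` and `n_genes`.
#' @export
bin_gene_cn <- function(genes) {
  cn <- genes$copy_number
  binned <- cut(cn, breaks = CN_BREAKS, labels = CN_LABELS, right = TRUE)
  counts <- table(binned)
  out <- tibble(
    bin = c(CN_LABELS, "Null"),
    count = c(as.integer(counts), sum(is.na(cn)))
  )
  attr(out, "ave_cn") <- if (any(!is.na(cn))) {
    round(mean(cn, na.rm = TRUE), 1)
  } else {
    NA_real_
  }
  attr(out, "n_genes") <- length(cn)
  class(out) <- c("cn_bin_table", class(out))
  out
}

#' @export
glance.cn_bin_table <- function(x, ...) {
  tibble(n_genes = attr(x, "n_genes"), ave_cn = attr(x, "ave_cn"))
}

#' Common SD genes across species
#'
#' Maps each species' SD gene set into a shared reference namespace
#' through its ortholog map and reports the genes present in at least
#' `min_species` species, together with Venn-style combination counts and
#' the full membership matrix.
#'
#' @param gene_sets Named list (one element per species) of character
#'   vectors of species gene ids.
#' @param ortholog_maps Named list (same names) of tibbles with columns
#'   `species_gene_id`, `reference_gene_id`; a species gene mapping to two
#'   reference ids is an error, unmapped genes are counted and dropped.
#' @param min_species Minimum number of species (default 5).
#' @return List: `common` (character vector of reference ids in at least
#'   `min_species` species), `membership` (tibble gene x species logical),
#'   `combination_counts` (tibble of species combinations and gene
#'   counts), `unmapped` (named integer vector).
#' @export
common_genes <- function(gene_sets, ortholog_maps, min_species = 5) {
  species <- names(gene_sets)
  if (is.null(species) || !setequal(species, names(ortholog_maps))) {
    stop_invalid("gene_sets and ortholog_maps must share species names")
  }
  if (length(species) < min_species) {
    stop_invalid("fewer species supplied than min_species")
  }
  mapped <- list()
  unmapped <- integer(0)
  for (sp in species) {
    m <- as_tibble(ortholog_maps[[sp]])
    if (!all(c("species_gene_id", "reference_gene_id") %in% names(m))) {
      stop_invalid("ortholog maps need species_gene_id and reference_gene_id")
    }
    conflict <- m |>
      distinct(.data$species_gene_id, .data$reference_gene_id) |>
      dplyr::count(.data$species_gene_id) |>
      filter(.data$n > 1)
    if (nrow(conflict) > 0) {
      stop_invalid(paste0("species gene(s) mapping to multiple reference ids in ",
                          sp, ": ", paste(head(conflict$species_gene_id, 3),
                                          collapse = ", ")))
    }
    ids <- unique(gene_sets[[sp]])
    hit <- m$reference_gene_id[match(ids, m$species_gene_id)]
    unmapped[sp] <- sum(is.na(hit))
    mapped[[sp]] <- unique(hit[!is.na(hit)])
  }
  if (sum(unmapped) > 0) {
    inform(paste("unmapped gene ids dropped:",
                 paste(names(unmapped), unmapped, sep = "=", collapse = ", ")))
  }
  all_ref <- sort(unique(unlist(mapped)))
  memb <- tibble(reference_gene_id = all_ref)
  for (sp in species) {
    memb[[sp]] <- all_ref %in% mapped[[sp]]
  }
  n_present <- rowSums(as.matrix(memb[species]))
  combo <- memb |>
    mutate(combination = apply(as.matrix(memb[species]), 1, function(r) {
      paste(species[r], collapse = "&")
    })) |>
    dplyr::count(.data$combination, name = "n_genes") |>
    arrange(dplyr::desc(.data$n_genes))
  list(
    common = memb$reference_gene_id[n_present >= min_species],
    membership = memb,
    combination_counts = combo,
    unmapped = unmapped
  )
}
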