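# Transposable-element enrichment and chromosome-scale signal profiles.

#' Transposable-element overlap and subfamily enrichment of a DMR set
#'
#' Reports, per change direction, the fraction of DMRs overlapping any
#' transposable element, and a per-subfamily enrichment table (window-based
#' [feature_enrichment()], computed separately on the hypermethylated and
#' hypomethylated DMR subsets) with the > 5-fold significance flag.
#'
#' @param dmrs Tibble of DMRs with `chrom`, `start`, `end`, `direction`.
#' @param te_catalog TE tibble (`chrom`, `start`, `end`, `subfamily`).
#' @param windows Window frame for the genomic background.
#' @return A list with `overall` (tibble `direction`, `n_dmr`, `n_te_overlap`,
#'   `frac_te`) and `by_subfamily` (enrichment tibble with a `direction`
#'   column), of class `te_enrichment`.
#' @export
te_enrichment_report <- function(dmrs, te_catalog, windows) {
  stopifnot(nrow(te_catalog) > 0)
  subfams <- split(te_catalog, te_catalog$subfamily)
  res <- map_dfr(c("hyper", "hypo"), function(dir) {
    d <- dmrs[dmrs$direction == dir, ]
    if (nrow(d) == 0) {
      return(tibble(direction = dir, n_dmr = 0L, n_te_overlap = 0L, frac_te = NA_real_))
    }
    tibble(direction = dir, n_dmr = nrow(d),
           n_te_overlap = sum(overlap_count(d, te_catalog) > 0)) |>
      mutate(frac_te = .data$n_te_overlap / .data$n_dmr)
  })
  by_sub <- map_dfr(c("hyper", "hypo"), function(dir) {
    d <- dmrs[dmrs$direction == dir, ]
    if (nrow(d) == 0) return(NULL)
    feature_enrichment(d, subfams, windows) |>
      mutate(direction = dir, .before = 1) |>
      rename(subfamily = "feature")
  })
  structure(list(overall = res, by_subfamily = by_sub), class = "te_enrichment")
}

bin_index <- function(windows, bin_width) {
  # windows never straddle a bin boundary when bin_width is a multiple of the
  # window width (the pipeline config enforces this)
  sprintf("%s:%09d", windows$chrom, windows$start %/% bin_width)
}

#' Binned RPKM profile and tumor/normal log2 fold change
#'
#' Aggregates window counts of each track into large bins and computes RPKM
#' (`count / (bin_kb x library_millions)`) per assay. Fold changes are
#' averaged across same-type tumor tracks on the RPKM scale before log2
#' transformation; bins where the reference has zero RPKM are reported
#' missing.
#'
#' @param tracks Named list of track tibbles (window frame + `medip`, `mre`).
#' @param reference Name of the reference (normal) track in `tracks`.
#' @param type_map Named character vector mapping track names to types (e.g.
#'   `c(EAC1 = "EAC", ...)`); tracks absent from the map are profiled but not
#'   averaged.
#' @param bin_width Bin width in bases (default 500 kb).
#' @return A list of class `rpkm_profile`: `rpkm` (tibble track x bin x assay)
#'   and `log2fc` (tibble type x bin x assay with `log2fc`).
#' @export
binned_rpkm_profile <- function(tracks, reference, type_map = NULL,
                                bin_width = 5e5) {
  stopifnot(reference %in% names(tracks))
  rpkm_one <- function(track, name) {
    bins <- bin_index(track, bin_width)
    track |>
      mutate(bin = bins) |>
      group_by(.data$chrom, .data$bin) |>
      summarise(bin_start = min(.data$start), bin_end = max(.data$end),
                medip = sum(.data$medip), mre = sum(.data$mre),
                .groups = "drop") |>
      tidyr::pivot_longer(c("medip", "mre"), names_to = "assay",
                          values_to = "count") |>
      mutate(track = name)
  }
  rpkm <- map_dfr(names(tracks), function(nm) rpkm_one(tracks[[nm]], nm))
  totals <- rpkm |>
    group_by(.data$track, .data$assay) |>
    summarise(lib = sum(.data$count), .groups = "drop")
  if (any(totals$lib <= 0)) abort("a track has zero library total")
  rpkm <- rpkm |>
    left_join(totals, by = c("track", "assay")) |>
    mutate(bin_kb = (.data$bin_end - .data$bin_start) / 1000,
           rpkm = .data$count / (.data$bin_kb * .data$lib / 1e6)) |>
    select("track", "chrom", "bin", "bin_start", "bin_end", "assay", "rpkm")
  ref <- rpkm |>
    filter(.data$track == reference) |>
    select("chrom", "bin", "assay", ref_rpkm = "rpkm")
  log2fc <- NULL
  if (!is.null(type_map)) {
    log2fc <- rpkm |>
      filter(.data$track %in% names(type_map)) |>
      mutate(type = unname(type_map[.data$track])) |>
      group_by(.data$type, .data$chrom, .data$bin, .data$bin_start,
               .data$bin_end, .data$assay) |>
      summarise(rpkm = mean(.data$rpkm), .groups = "drop") |>
      left_join(ref, by = c("chrom", "bin", "assay")) |>
      mutate(log2fc = ifelse(.data$ref_rpkm > 0,
                             log2(.data$rpkm / .data$ref_rpkm), NA_real_))
  }
  structure(list(rpkm = rpkm, log2fc = log2fc), class = "rpkm_profile")
}

#' Genome fractions with shifted MeDIP signal density
#'
#' Compares the normalized (library-scaled) MeDIP signal of each tumor against
#' the normal track in large bins. A bin is hypomethylated when the
#' tumor/normal density ratio is at most `1/fold_threshold` and
#' hypermethylated when it is at least `fold_threshold`; fractions are taken
#' over bins with nonzero normal signal, then averaged per tumor type.
#'
#' @param tumor_tracks Named list of tumor track tibbles.
#' @param normal_track The normal track tibble.
#' @param type_map Named character vector mapping tumor names to types.
#' @param bin_width Bin width in bases (default 5 kb).
#' @param fold_threshold Density-ratio threshold (> 1, default 2).
#' @param normalize Scale each track by its library total before comparing
#'   (default `TRUE`); set `FALSE` to compare raw binned counts when tracks
#'   are already on a common scale.
#' @return A list of class `density_shift`: `per_sample` (tibble `track`,
#'   `type`, `frac_hypo`, `frac_hyper`, `n_bins`) and `per_type` (the same
#'   fractions averaged within type).
#' @export
global_density_shift <- function(tumor_tracks, normal_track, type_map,
                                 bin_width = 5000, fold_threshold = 2,
                                 normalize = TRUE) {
  stopifnot(fold_threshold > 1)
  bin_counts <- function(track) {
    track |>
      mutate(bin = bin_index(track, bin_width)) |>
      group_by(.data$bin) |>
      summarise(medip = sum(.data$medip), .groups = "drop")
  }
  nb <- bin_counts(normal_track)
  n_density <- if (normalize) nb$medip / sum(nb$medip) else nb$medip
  per_sample <- map_dfr(names(tumor_tracks), function(nm) {
    tb <- bin_counts(tumor_tracks[[nm]])
    stopifnot(identical(tb$bin, nb$bin))
    t_density <- if (normalize) tb$medip / sum(tb$medip) else tb$medip
    ok <- n_density > 0
    ratio <- t_density[ok] / n_density[ok]
    tibble(track = nm, type = unname(type_map[nm]),
           frac_hypo = mean(ratio <= 1 / fold_threshold),
           frac_hyper = mean(ratio >= fold_threshold),
           n_bins = sum(ok))
  })
  per_type <- per_sample |>
    group_by(.data$type) |>
    summarise(frac_hypo = mean(.data$frac_hypo),
              frac_hyper = mean(.data$frac_hyper), .groups = "drop")
  structure(list(per_sample = per_sample, per_type = per_type),
            class = "density_shift")
}
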