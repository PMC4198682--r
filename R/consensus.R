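# Consensus rules across pairwise tumor-vs-normal calls: recurrence (>= 2 of
# 3 concordant), shared across cancer types, and type-preferred (all 3 of one
# type, none of the other).

#' Consensus DMRs of one cancer type
#'
#' A window is a consensus DMR iff at least `min_support` of the type's
#' pairwise comparisons call it with the same direction. A 2-vs-1 direction
#' conflict resolves to the majority direction iff the majority reaches
#' `min_support`; direction ties yield no call.
#'
#' @param calls List of pairwise call tibbles (from [call_pairwise_dmrs()]),
#'   one per tumor-vs-normal comparison of the type.
#' @param min_support Minimum number of concordant calls (default 2).
#' @return A tibble with `win_id`, `direction`, `support` (concordant calls),
#'   `n_called` (calls of either direction), and the window coordinates if
#'   present in the inputs.
#' @export
consensus_dmrs <- function(calls, min_support = 2L) {
  tab <- bind_rows(calls) |>
    count(.data$win_id, .data$direction, name = "votes") |>
    tidyr::pivot_wider(names_from = "direction", values_from = "votes",
                       values_fill = 0L)
  for (col in c("hyper", "hypo")) if (!col %in% names(tab)) tab[[col]] <- 0L
  out <- tab |>
    mutate(n_called = .data$hyper + .data$hypo,
           support = pmax(.data$hyper, .data$hypo),
           direction = case_when(.data$hyper > .data$hypo ~ "hyper",
                                 .data$hypo > .data$hyper ~ "hypo",
                                 TRUE ~ NA_character_)) |>
    filter(.data$support >= min_support, !is.na(.data$direction)) |>
    select("win_id", "direction", "support", "n_called") |>
    arrange(.data$win_id)
  coords <- bind_rows(calls)
  if (all(c("chrom", "start", "end") %in% names(coords)) && nrow(coords) > 0) {
    out <- out |>
      left_join(distinct(coords, .data$win_id, .data$chrom, .data$start, .data$end),
                by = "win_id") |>
      relocate("chrom", "start", "end")
  }
  out
}

#' Cancer-type-shared consensus DMRs
#'
#' Windows that are consensus DMRs in both types with the same direction.
#'
#' @param eac_consensus,upsc_consensus Outputs of [consensus_dmrs()] on the
#'   same window frame.
#' @return A tibble with `win_id`, `direction`, per-type supports, and window
#'   coordinates when available.
#' @export
shared_dmrs <- function(eac_consensus, upsc_consensus) {
  inner_join(eac_consensus, upsc_consensus, by = c("win_id", "direction"),
             suffix = c("_eac", "_upsc")) |>
    select(any_of(c("chrom_eac", "start_eac", "end_eac")),
           "win_id", "direction", "support_eac", "support_upsc") |>
    rename_with(~sub("_eac$", "", .x), any_of(c("chrom_eac", "start_eac", "end_eac"))) |>
    arrange(.data$win_id)
}

#' Type-preferred DMRs
#'
#' A window is an EAC type-preferred DMR iff it is called with one concordant
#' direction in all EAC comparisons and called in no UPSC comparison (either
#' direction); symmetrically for UPSC.
#'
#' @param eac_calls,upsc_calls Lists of pairwise call tibbles per type.
#' @return A list with elements `EAC` and `UPSC`, each a tibble like
#'   [consensus_dmrs()] output with `support` equal to the number of
#'   comparisons of the owning type.
#' @export
type_preferred_dmrs <- function(eac_calls, upsc_calls) {
  one_side <- function(own, other) {
    n_own <- length(own)
    cons <- consensus_dmrs(own, min_support = n_own)
    called_other <- unique(bind_rows(other)$win_id)
    cons[!(cons$win_id %in% called_other), ]
  }
  list(EAC = one_side(eac_calls, upsc_calls),
       UPSC = one_side(upsc_calls, eac_calls))
}

#' Direction fractions and class totals from component DMR counts
#'
#' The summarizer behind headline "x% hypermethylated / y% hypomethylated"
#' statements: given per-class hyper/hypo counts it computes class totals and
#' direction percentages.
#'
#' @param counts Tibble with columns `class`, `n_hyper`, `n_hypo`.
#' @return The input with `total`, `pct_hyper`, `pct_hypo` added (percentages
#'   on the 0-100 scale).
#' @export
direction_fractions <- function(counts) {
  stopifnot(all(c("class", "n_hyper", "n_hypo") %in% names(counts)))
  counts |>
    mutate(total = .data$n_hyper + .data$n_hypo,
           pct_hyper = 100 * .data$n_hyper / .data$total,
           pct_hypo = 100 * .data$n_hypo / .data$total)
}

#' Summarize consensus DMR sets by class and direction
#'
#' @param ... Named consensus DMR tibbles (e.g. `EAC = ..., UPSC = ...,
#'   `EC_shared` = ...`), each with a `direction` column.
#' @return A tibble from [direction_fractions()] with one row per class.
#' @export
summarize_dmr_classes <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  map_dfr(names(sets), function(nm) {
    x <- sets[[nm]]
    tibble(class = nm,
           n_hyper = sum(x$direction == "hyper"),
           n_hypo = sum(x$direction == "hypo"))
  }) |>
    direction_fractions()
}

#' Merge adjacent same-direction DMR windows into regions
#'
#' DMRs are reported at window resolution by default; this optional step
#' collapses runs of adjacent windows with the same direction into single
#' regions (support is the maximum over the run). It is not applied anywhere
#' automatically.
#'
#' @param dmrs Consensus DMR tibble with `chrom`, `start`, `end`, `win_id`,
#'   `direction` (and optionally `support`).
#' @return A tibble with one row per merged region: `chrom`, `start`, `end`,
#'   `direction`, `n_windows`, `support`.
#' @export
merge_adjacent_dmrs <- function(dmrs) {
  if (nrow(dmrs) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  direction = character(), n_windows = integer(),
                  support = integer()))
  }
  dmrs |>
    arrange(.data$win_id) |>
    group_by(.data$chrom, .data$direction) |>
    mutate(run = cumsum(c(1L, diff(.data$win_id) != 1L))) |>
    group_by(.data$chrom, .data$direction, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = dplyr::n(),
              support = if ("support" %in% names(dmrs)) max(.data$support) else NA_integer_,
              .groups = "drop") |>
    select("chrom", "start", "end", "direction", "n_windows", "support") |>
    arrange(.data$chrom, .data$start)
}
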