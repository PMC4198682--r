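# Chromatin-state annotation of windows: per-cell-line dominant state,
# promoter-precedence merging across cell lines, and developmental methylation
# patterns against an embryonic-stem-cell reference.

#' Dominant chromatin state of each window in one cell line
#'
#' The dominant state is the state covering more than 50% of the window's
#' bases; if no state exceeds 50% (e.g. an exact 250/250 bp tie) the window
#' gets no dominant state.
#'
#' @param windows Window frame tibble (`chrom`, `start`, `end`, `win_id`).
#' @param segments Chromatin-state segments of one cell line (`chrom`,
#'   `start`, `end`, `state`), non-overlapping.
#' @return A tibble `win_id`, `state` (`NA` when no state dominates).
#' @export
dominant_state <- function(windows, segments) {
  hits <- overlap_join(windows, segments)
  width <- (windows$end - windows$start)[hits$query]
  cover <- tibble(win_id = windows$win_id[hits$query],
                  state = segments$state[hits$subject],
                  frac = hits$overlap / width) |>
    group_by(.data$win_id, .data$state) |>
    summarise(frac = sum(.data$frac), .groups = "drop_last") |>
    slice_max(.data$frac, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(state = ifelse(.data$frac > 0.5, .data$state, NA_character_))
  tibble(win_id = windows$win_id) |>
    left_join(select(cover, "win_id", "state"), by = "win_id")
}

#' Merge per-cell-line dominant states into a regulatory class
#'
#' A window is `promoter` if its dominant state maps to a promoter state in at
#' least one cell line; otherwise `enhancer` if any cell line's dominant state
#' maps to an enhancer state; otherwise `other`. Promoter precedence means a
#' window can never be labeled enhancer while any cell line shows a promoter
#' dominant state.
#'
#' @param dominant_states Tibble with `win_id`, `state`, `cell_line` (stacked
#'   [dominant_state()] outputs).
#' @param state_map Named character vector state label -> class in
#'   {`promoter`, `enhancer`, `other`} (see [default_state_map()]). Must cover
#'   every observed label.
#' @return A tibble `win_id`, `reg_class`.
#' @export
merge_states <- function(dominant_states, state_map = default_state_map()) {
  observed <- unique(dominant_states$state[!is.na(dominant_states$state)])
  unmapped <- setdiff(observed, names(state_map))
  if (length(unmapped) > 0) {
    abort(paste0("state_map does not cover: ", paste(unmapped, collapse = ", ")))
  }
  dominant_states |>
    mutate(class = ifelse(is.na(.data$state), "other",
                          unname(state_map[.data$state]))) |>
    group_by(.data$win_id) |>
    summarise(reg_class = if (any(.data$class == "promoter")) "promoter"
              else if (any(.data$class == "enhancer")) "enhancer"
              else "other",
              .groups = "drop")
}

#' Developmental methylation pattern of a cancer DMR
#'
#' Three-letter words over (embryonic stem cells, normal tissue, cancer), M =
#' methylated / U = unmethylated. A cancer hypomethylated DMR implies the
#' normal tissue is methylated there; a hypermethylated DMR implies it is
#' unmethylated. The stem-cell letter comes from the stem-cell-vs-normal
#' comparison at the same window: `none` (no difference), `NE-higher` (normal
#' more methylated than stem cells) or `NE-lower`.
#'
#' * hypo + `none` -> MMU, hypo + `NE-higher` -> UMU
#' * hyper + `none` -> UUM, hyper + `NE-lower` -> MUM
#'
#' @param cancer_direction Character vector in {`hyper`, `hypo`}.
#' @param h1_vs_ne_call Character vector in {`NE-higher`, `NE-lower`, `none`}.
#' @return Character vector of patterns (`NA` for inconsistent combinations,
#'   e.g. hypo + `NE-lower`).
#' @export
methylation_pattern <- function(cancer_direction, h1_vs_ne_call) {
  stopifnot(all(cancer_direction %in% c("hyper", "hypo")),
            all(h1_vs_ne_call %in% c("NE-higher", "NE-lower", "none")))
  case_when(
    cancer_direction == "hypo" & h1_vs_ne_call == "none" ~ "MMU",
    cancer_direction == "hypo" & h1_vs_ne_call == "NE-higher" ~ "UMU",
    cancer_direction == "hyper" & h1_vs_ne_call == "none" ~ "UUM",
    cancer_direction == "hyper" & h1_vs_ne_call == "NE-lower" ~ "MUM",
    TRUE ~ NA_character_
  )
}

#' Pattern calls for a consensus DMR set
#'
#' Derives the stem-cell-vs-normal letter from an H1-vs-NE pairwise call set
#' and maps every consensus DMR to its developmental pattern, then attaches
#' the merged chromatin regulatory class.
#'
#' @param consensus Consensus DMR tibble with `win_id`, `direction`.
#' @param h1_calls Pairwise call tibble of the H1-vs-NE comparison
#'   ([call_pairwise_dmrs()] with H1 as "tumor"): a `hyper` call means H1 is
#'   more methylated than NE (`NE-lower`), `hypo` means `NE-higher`.
#' @param reg_class Optional [merge_states()] output to join on `win_id`.
#' @return `consensus` with `pattern` (and `reg_class` when supplied) added.
#' @export
pattern_calls <- function(consensus, h1_calls, reg_class = NULL) {
  h1 <- tibble(win_id = h1_calls$win_id,
               h1_state = ifelse(h1_calls$direction == "hyper", "NE-lower", "NE-higher"))
  out <- consensus |>
    left_join(h1, by = "win_id") |>
    mutate(h1_state = ifelse(is.na(.data$h1_state), "none", .data$h1_state),
           pattern = methylation_pattern(.data$direction, .data$h1_state)) |>
    select(-"h1_state")
  if (!is.null(reg_class)) out <- left_join(out, reg_class, by = "win_id")
  out
}
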