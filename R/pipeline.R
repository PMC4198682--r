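# End-to-end pipeline: simulate -> call -> consensus -> annotate -> validate,
# fully deterministic under one seed.

#' Pipeline configuration
#'
#' Aggregates every tunable constant of the pipeline: the 500 bp analysis
#' window, the q < 1e-5 pairwise call cutoff, the >= 2-of-3 recurrence rule,
#' the cohort validation thresholds (q < 0.05, |DMC| > 0.05), and the 5 kb /
#' 500 kb profile resolutions.
#'
#' @param window_width Analysis window width in bases.
#' @param q_cutoff Pairwise DMR q-value cutoff.
#' @param min_support Concordant calls required for a type consensus.
#' @param val_q,val_dmc Cohort validation thresholds.
#' @param density_bin,profile_bin Bin widths for the global density comparison
#'   and the chromosome RPKM profile.
#' @param fold_threshold Density-ratio threshold of the global comparison.
#' @param seed Master seed; all stage seeds derive from it.
#' @param genome A [genome_config()].
#' @param design A [methylome_design()].
#' @param depth A [depth_config()].
#' @param cohort A [cohort_config()].
#' @param n_cell_lines Chromatin-state cell lines to simulate.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_width = 500L, q_cutoff = 1e-5,
                            min_support = 2L, val_q = 0.05, val_dmc = 0.05,
                            density_bin = 5000L, profile_bin = 5e5,
                            fold_threshold = 2, seed = 1L,
                            genome = genome_config(window_width = window_width),
                            design = methylome_design(),
                            depth = depth_config(),
                            cohort = cohort_config(),
                            n_cell_lines = 2L) {
  stopifnot(q_cutoff >= 0, min_support >= 1, val_q > 0, val_dmc > 0,
            density_bin %% window_width == 0, profile_bin %% window_width == 0)
  structure(list(window_width = as.integer(window_width), q_cutoff = q_cutoff,
                 min_support = as.integer(min_support), val_q = val_q,
                 val_dmc = val_dmc, density_bin = density_bin,
                 profile_bin = profile_bin, fold_threshold = fold_threshold,
                 seed = as.integer(seed), genome = genome, design = design,
                 depth = depth, cohort = cohort,
                 n_cell_lines = as.integer(n_cell_lines)),
            class = "pipeline_config")
}

stage_seed <- function(seed, k) (seed * 101L + k * 7919L) %% 2147483647L

#' Run the full synthetic-data pipeline
#'
#' Generates a toy genome, plants latent methylomes, simulates dual-assay
#' count tracks, calls pairwise DMRs for each tumor (and for H1) against the
#' pooled normal, forms type consensus / shared / type-preferred sets,
#' annotates context, chromatin regulatory class, developmental patterns, TE
#' enrichment and chromosome profiles, simulates an array-like cohort and
#' validates the shared DMRs in it, and scores recovery against the planted
#' truth.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `meth_pipeline` with elements `genome`, `latent`,
#'   `tracks`, `calls` (per comparison), `consensus` (EAC/UPSC/shared/tp),
#'   `annotated`, `te`, `profile`, `density`, `cohort`, `validation`,
#'   `recovery`, `summary`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  genome <- generate_genome(cfg$genome, seed = stage_seed(cfg$seed, 1L))
  latent <- plant_methylomes(genome, cfg$design, seed = stage_seed(cfg$seed, 2L))
  tracks <- simulate_counts(latent, cfg$depth, seed = stage_seed(cfg$seed, 3L))
  segments <- simulate_chromhmm(genome, cfg$n_cell_lines,
                                seed = stage_seed(cfg$seed, 4L))
  cohort <- simulate_probe_cohort(latent, genome, cfg$cohort,
                                  seed = stage_seed(cfg$seed, 5L))

  tumors <- latent$samples$sample[latent$samples$group %in% c("EAC", "UPSC")]
  calls <- lapply(c(tumors, "H1"), function(s) {
    call_pairwise_dmrs(tracks$NE, tracks[[s]], q_cutoff = cfg$q_cutoff)
  })
  names(calls) <- c(tumors, "H1")
  eac_calls <- calls[grep("^EAC", names(calls))]
  upsc_calls <- calls[grep("^UPSC", names(calls))]

  eac <- consensus_dmrs(eac_calls, cfg$min_support)
  upsc <- consensus_dmrs(upsc_calls, cfg$min_support)
  shared <- shared_dmrs(eac, upsc)
  tp <- type_preferred_dmrs(eac_calls, upsc_calls)

  catalog <- feature_catalog(genome)
  dom <- map_dfr(unique(segments$cell_line), function(cl) {
    dominant_state(genome$windows, segments[segments$cell_line == cl, ]) |>
      mutate(cell_line = cl)
  })
  reg <- merge_states(dom)
  annotated <- lapply(list(EAC = eac, UPSC = upsc), function(cons) {
    cons |>
      classify_context(catalog) |>
      pattern_calls(calls$H1, reg)
  })

  te <- lapply(annotated, function(a) {
    te_enrichment_report(a, catalog$te, genome$windows)
  })
  type_map <- setNames(latent$samples$group[match(tumors, latent$samples$sample)],
                       tumors)
  profile <- binned_rpkm_profile(tracks, reference = "NE", type_map = type_map,
                                 bin_width = cfg$profile_bin)
  density <- global_density_shift(tracks[tumors], tracks$NE, type_map,
                                  bin_width = cfg$density_bin,
                                  fold_threshold = cfg$fold_threshold)

  validation <- validate_dmrs(shared, cohort, cancer_group = "EAC",
                              q_cutoff = cfg$val_q, dmc_cutoff = cfg$val_dmc)
  coverage <- probe_coverage(bind_rows(EAC = annotated$EAC, UPSC = annotated$UPSC,
                                       .id = "type"),
                             cohort$probes)

  recovery <- score_recovery(latent$truth, list(EAC = eac, UPSC = upsc,
                                                shared = shared))
  summary <- list(
    classes = summarize_dmr_classes(EAC = eac, UPSC = upsc, EC_shared = shared),
    context = lapply(annotated, function(a) table(a$context)),
    patterns = lapply(annotated, function(a) table(a$pattern, useNA = "ifany")),
    coverage = coverage,
    validation_rate = mean(validation$validated[validation$testable]),
    recovery = recovery,
    density = density$per_type,
    seed = cfg$seed
  )
  structure(list(genome = genome, latent = latent, tracks = tracks,
                 calls = calls, consensus = list(EAC = eac, UPSC = upsc,
                                                 shared = shared, tp = tp),
                 annotated = annotated, te = te, profile = profile,
                 density = density, cohort = cohort, validation = validation,
                 recovery = recovery, summary = summary, config = cfg),
            class = "meth_pipeline")
}

#' Score planted-DMR recovery of consensus call sets
#'
#' Sensitivity is the fraction of planted windows of each class recovered by
#' the matching consensus set (shared DMRs count for both types); direction
#' accuracy is the fraction of recovered windows with the planted direction.
#'
#' @param truth Truth tibble from [plant_methylomes()].
#' @param consensus List with `EAC`, `UPSC` and `shared` consensus tibbles.
#' @return A tibble `class`, `n_planted`, `n_recovered`, `sensitivity`,
#'   `direction_accuracy`.
#' @export
score_recovery <- function(truth, consensus) {
  lookup <- list(EAC = consensus$EAC, UPSC = consensus$UPSC,
                 shared = bind_rows(consensus$EAC, consensus$UPSC))
  map_dfr(c("EAC", "UPSC", "shared"), function(cl) {
    t <- truth[truth$class == cl, ]
    cons <- lookup[[cl]]
    hit <- t$win_id %in% cons$win_id
    dir_ok <- cons$direction[match(t$win_id, cons$win_id)] == t$direction
    tibble(class = cl, n_planted = nrow(t), n_recovered = sum(hit),
           sensitivity = mean(hit),
           direction_accuracy = ifelse(any(hit), mean(dir_ok[hit]), NA_real_))
  })
}

#' @export
print.meth_pipeline <- function(x, ...) {
  cat("<meth_pipeline> seed", x$config$seed, "\n")
  print(x$summary$classes)
  cat("recovery:\n")
  print(x$recovery)
  cat(sprintf("cohort validation rate (testable shared DMRs): %.3f\n",
              x$summary$validation_rate))
  invisible(x)
}

#' Tidy the per-class consensus table of a pipeline run
#'
#' @param x A `meth_pipeline`.
#' @param ... Unused.
#' @return One row per DMR class with counts and direction percentages.
#' @method tidy meth_pipeline
#' @export
tidy.meth_pipeline <- function(x, ...) {
  as_tibble(x$summary$classes)
}

#' One-row summary of a pipeline run
#'
#' @param x A `meth_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble: consensus counts, overall sensitivity, direction
#'   accuracy, validation rate.
#' @method glance meth_pipeline
#' @export
glance.meth_pipeline <- function(x, ...) {
  rec <- x$recovery
  tibble(n_eac = nrow(x$consensus$EAC),
         n_upsc = nrow(x$consensus$UPSC),
         n_shared = nrow(x$consensus$shared),
         n_tp_eac = nrow(x$consensus$tp$EAC),
         n_tp_upsc = nrow(x$consensus$tp$UPSC),
         sensitivity = sum(rec$n_recovered) / sum(rec$n_planted),
         direction_accuracy = stats::weighted.mean(rec$direction_accuracy,
                                                   rec$n_recovered, na.rm = TRUE),
         validation_rate = x$summary$validation_rate,
         seed = x$config$seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
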