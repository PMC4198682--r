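# Latent methylomes with planted DMRs, dual-assay Poisson count tracks, and an
# Infinium-like beta-value validation cohort.

#' Design of the planted-DMR experiment
#'
#' Defaults emulate a study with one pooled-normal methylome (NE), three
#' tumors of each of two types (EAC1-3, UPSC1-3) and one embryonic-stem-cell
#' profile (H1): 60 planted DMR windows per class (EAC-preferred,
#' UPSC-preferred, shared), half hypermethylated and half hypomethylated, with
#' effect size `delta` = 0.6 on the latent methylation scale, plus a contiguous
#' hypomethylated block covering ~55% of the X-like chromosome in UPSC only.
#' Baseline normal methylation is low (~0.1) in CpG-island/promoter windows and
#' high (~0.8) elsewhere. DMRs are planted only in windows carrying at least
#' `plant_cpg_min` CpGs (about twice the genome-mean density): a window with
#' almost no CpGs carries no methylation information in either assay, and real
#' DMRs concentrate at CpG-supported loci (islands, shores, CpG-bearing
#' transposable elements).
#'
#' @param n_eac,n_upsc,n_shared Planted windows per class.
#' @param frac_hyper Fraction of each class planted as hypermethylated.
#' @param delta Latent methylation effect size in (0, 1].
#' @param baseline_low,baseline_high Baseline normal methylation inside and
#'   outside CpG-island/promoter windows.
#' @param jitter_sd Per-sample Gaussian jitter on latent methylation.
#' @param plant_cpg_min Minimum per-window CpG count for a planted DMR.
#' @param x_block_span Start/end of the hypomethylated block as fractions of
#'   the X-like chromosome.
#' @param x_block_delta Latent hypomethylation depth of the block (UPSC only).
#' @param cnv_blocks Number of copy-number blocks per tumor sample (each ~20
#'   windows, alternating factor 2 and 0.5); 0 disables CNV.
#' @return A list of class `methylome_design`.
#' @export
methylome_design <- function(n_eac = 60L, n_upsc = 60L, n_shared = 60L,
                             frac_hyper = 0.5, delta = 0.6,
                             baseline_low = 0.1, baseline_high = 0.8,
                             jitter_sd = 0.03, plant_cpg_min = 10L,
                             x_block_span = c(0.25, 0.80),
                             x_block_delta = 0.3,
                             cnv_blocks = 2L) {
  stopifnot(delta > 0, delta <= 1, frac_hyper >= 0, frac_hyper <= 1)
  structure(list(n_eac = n_eac, n_upsc = n_upsc, n_shared = n_shared,
                 frac_hyper = frac_hyper, delta = delta,
                 baseline_low = baseline_low, baseline_high = baseline_high,
                 jitter_sd = jitter_sd, plant_cpg_min = plant_cpg_min,
                 x_block_span = x_block_span, x_block_delta = x_block_delta,
                 cnv_blocks = cnv_blocks),
            class = "methylome_design")
}

sample_names <- function() c("NE", paste0("EAC", 1:3), paste0("UPSC", 1:3), "H1")

#' Plant latent methylomes and a truth set on a toy genome
#'
#' Assigns a baseline normal (NE) methylation level per window, plants DMRs of
#' each class (EAC-preferred, UPSC-preferred, shared) at disjoint windows,
#' lowers a contiguous block of the X-like chromosome in UPSC samples only, and
#' gives the H1 profile designed departures from NE so that all four
#' developmental patterns (MMU, MUM, UMU, UUM) arise among planted DMRs:
#' hypermethylated DMRs split between H1-high (MUM) and H1-low (UUM), and
#' hypomethylated DMRs between H1-low (UMU) and H1-high (MMU).
#'
#' @param genome A [generate_genome()] result.
#' @param design A [methylome_design()].
#' @param seed Integer seed.
#' @return A list of class `latent_methylome` with elements `windows`,
#'   `group_m` (windows x groups NE/EAC/UPSC/H1 latent levels, jitter-free),
#'   `m` (windows x samples with per-sample jitter), `cnv` (windows x samples,
#'   1 for NE and H1), `samples` (tibble `sample`, `group`) and `truth`
#'   (tibble `win_id`, `class`, `direction`, `delta`, `pattern`).
#' @export
plant_methylomes <- function(genome, design = methylome_design(), seed = 1L) {
  set.seed(seed)
  w <- genome$windows
  n <- nrow(w)
  low_windows <- unique(c(intervals_to_windows(genome$cgis, w)$win_id,
                          intervals_to_windows(genome$promoters, w)$win_id))
  base <- ifelse(w$win_id %in% low_windows, design$baseline_low, design$baseline_high)

  eligible_hyper <- w$win_id[base <= 1 - design$delta & w$cpg_count >= design$plant_cpg_min]
  eligible_hypo <- w$win_id[base >= design$delta & w$cpg_count >= design$plant_cpg_min]
  # keep the X-like block free of per-window planted DMRs so classes stay clean
  x_win <- w$win_id[w$chrom == genome$x_like_chrom]
  block_lo <- stats::quantile(x_win, design$x_block_span[1], type = 1)
  block_hi <- stats::quantile(x_win, design$x_block_span[2], type = 1)
  block <- x_win[x_win >= block_lo & x_win <= block_hi]
  eligible_hyper <- setdiff(eligible_hyper, block)
  eligible_hypo <- setdiff(eligible_hypo, block)

  classes <- c(EAC = design$n_eac, UPSC = design$n_upsc, shared = design$n_shared)
  n_hyper <- round(classes * design$frac_hyper)
  n_hypo <- classes - n_hyper
  if (sum(n_hyper) > length(eligible_hyper) || sum(n_hypo) > length(eligible_hypo)) {
    abort("requested planted windows exceed available eligible windows")
  }
  pick_hyper <- sample(eligible_hyper, sum(n_hyper))
  pick_hypo <- sample(eligible_hypo, sum(n_hypo))
  truth <- bind_rows(
    tibble(win_id = pick_hyper, direction = "hyper",
           class = rep(names(classes), n_hyper)),
    tibble(win_id = pick_hypo, direction = "hypo",
           class = rep(names(classes), n_hypo))
  )
  truth$delta <- design$delta
  # H1 design: per direction, half the planted DMRs get an H1 level opposite
  # to NE, producing the four developmental patterns
  truth <- truth |>
    group_by(.data$direction) |>
    mutate(h1_opposite = seq_along(.data$win_id) %% 2L == 0L) |>
    ungroup() |>
    mutate(pattern = case_when(
      .data$direction == "hyper" & .data$h1_opposite ~ "MUM",
      .data$direction == "hyper" & !.data$h1_opposite ~ "UUM",
      .data$direction == "hypo" & .data$h1_opposite ~ "UMU",
      TRUE ~ "MMU"
    ))

  effect <- function(groups) {
    # groups: character vector of classes affecting this group
    delta_vec <- numeric(n)
    rows <- truth[truth$class %in% groups, ]
    delta_vec[rows$win_id] <- ifelse(rows$direction == "hyper", rows$delta, -rows$delta)
    delta_vec
  }
  m_ne <- base
  m_eac <- pmin(pmax(base + effect(c("EAC", "shared")), 0), 1)
  m_upsc <- pmin(pmax(base + effect(c("UPSC", "shared")), 0), 1)
  if (design$x_block_delta > 0) {
    m_upsc[block] <- pmax(m_upsc[block] - design$x_block_delta, 0.02)
  }
  m_h1 <- base
  h1_rows <- truth[truth$h1_opposite, ]
  m_h1[h1_rows$win_id] <- ifelse(h1_rows$direction == "hyper",
                                 pmin(base[h1_rows$win_id] + design$delta, 1),
                                 pmax(base[h1_rows$win_id] - design$delta, 0))

  truth <- truth |> select(-"h1_opposite")
  if (design$x_block_delta > 0) {
    truth <- bind_rows(truth,
                       tibble(win_id = block, direction = "hypo", class = "x_block",
                              delta = design$x_block_delta, pattern = NA_character_))
  }

  samples <- tibble(sample = sample_names(),
                    group = c("NE", rep("EAC", 3), rep("UPSC", 3), "H1"))
  group_m <- cbind(NE = m_ne, EAC = m_eac, UPSC = m_upsc, H1 = m_h1)
  m <- vapply(seq_len(nrow(samples)), function(i) {
    g <- samples$group[i]
    jit <- if (g == "NE") 0 else rnorm(n, 0, design$jitter_sd)
    pmin(pmax(group_m[, g] + jit, 0), 1)
  }, numeric(n))
  colnames(m) <- samples$sample

  cnv <- matrix(1, nrow = n, ncol = nrow(samples),
                dimnames = list(NULL, samples$sample))
  if (design$cnv_blocks > 0) {
    planted <- truth$win_id
    for (s in samples$sample[samples$group %in% c("EAC", "UPSC")]) {
      for (b in seq_len(design$cnv_blocks)) {
        repeat {
          s0 <- sample.int(n - 20L, 1L)
          ids <- s0:(s0 + 19L)
          if (!any(ids %in% planted)) break
        }
        cnv[ids, s] <- if (b %% 2L == 1L) 2 else 0.5
      }
    }
  }

  structure(list(windows = w, group_m = group_m, m = m, cnv = cnv,
                 samples = samples, truth = truth, design = design),
            class = "latent_methylome")
}

#' Sequencing-depth configuration for the count simulator
#'
#' `medip` and `mre` are the expected reads per 500 bp window per assay for a
#' fully methylated (respectively fully unmethylated) window of genome-average
#' CpG (respectively MRE-site) density.
#'
#' @param medip,mre Expected reads per window per assay.
#' @return A list of class `depth_config`.
#' @export
depth_config <- function(medip = 30, mre = 30) {
  stopifnot(medip >= 0, mre >= 0)
  structure(list(medip = medip, mre = mre), class = "depth_config")
}

#' Simulate dual-assay count tracks from a latent methylome
#'
#' Per window and sample, MeDIP counts are Poisson with mean
#' `d_medip * cnv * m * cpg_count / cpg_ref` and MRE counts are Poisson with
#' mean `d_mre * cnv * (1 - m) * mre_site_count / mre_ref`, where `cpg_ref`
#' and `mre_ref` are the genome-mean per-window densities. Windows without
#' CpGs receive zero counts in both assays.
#'
#' @param latent A [plant_methylomes()] result.
#' @param depth A [depth_config()].
#' @param seed Integer seed.
#' @return Named list of per-sample track tibbles, each the window frame plus
#'   `medip`, `mre`, `cnv` and a `sample` column.
#' @export
simulate_counts <- function(latent, depth = depth_config(), seed = 1L) {
  set.seed(seed)
  w <- latent$windows
  cpg_ref <- mean(w$cpg_count)
  mre_ref <- mean(w$mre_site_count)
  stopifnot(cpg_ref > 0, mre_ref > 0)
  out <- lapply(latent$samples$sample, function(s) {
    m <- latent$m[, s]
    cnv <- latent$cnv[, s]
    mu_medip <- depth$medip * cnv * m * w$cpg_count / cpg_ref
    mu_mre <- depth$mre * cnv * (1 - m) * w$mre_site_count / mre_ref
    mu_medip[w$cpg_count == 0] <- 0
    mu_mre[w$cpg_count == 0] <- 0
    mutate(w, medip = rpois(nrow(w), mu_medip), mre = rpois(nrow(w), mu_mre),
           cnv = cnv, sample = s)
  })
  setNames(out, latent$samples$sample)
}

#' Configuration of the Infinium-like validation cohort
#'
#' @param n_normal,n_eac,n_upsc Samples per group.
#' @param probes_per_kb Average probe density over the genome.
#' @param cgi_bias Relative probe-placement weight for CpGs inside CpG islands
#'   or core promoters (emulating the array's promoter/CGI design bias).
#' @param precision Beta-distribution precision (shape1 + shape2); the
#'   beta value's mean equals the group latent methylation and its variance
#'   shrinks as precision grows.
#' @param zero_probe_frac Fraction of planted DMR windows forced to carry no
#'   probes (exercises probe-coverage reporting).
#' @param missing_rate Fraction of beta values set missing at random.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_normal = 20L, n_eac = 20L, n_upsc = 20L,
                          probes_per_kb = 0.5, cgi_bias = 3,
                          precision = 50, zero_probe_frac = 0.3,
                          missing_rate = 0.02) {
  stopifnot(n_normal > 0, n_eac > 0, n_upsc > 0, precision > 0)
  structure(list(n_normal = n_normal, n_eac = n_eac, n_upsc = n_upsc,
                 probes_per_kb = probes_per_kb, cgi_bias = cgi_bias,
                 precision = precision, zero_probe_frac = zero_probe_frac,
                 missing_rate = missing_rate),
            class = "cohort_config")
}

#' Simulate an Infinium-like beta-value cohort
#'
#' Probes are placed at CpG positions with a configurable bias toward CpG
#' islands and core promoters. Each probe/sample beta value is drawn from a
#' Beta distribution whose mean is the sample group's latent methylation at the
#' probe's window. A configurable fraction of planted DMR windows is stripped
#' of probes.
#'
#' @param latent A [plant_methylomes()] result.
#' @param genome The [generate_genome()] result the latent methylome was built
#'   on.
#' @param cohort A [cohort_config()].
#' @param seed Integer seed.
#' @return A list of class `beta_cohort`: `probes` (tibble `probe_id`, `chrom`,
#'   `pos`, `win_id`), `beta` (probes x samples matrix, possibly with `NA`),
#'   `groups` (tibble `sample`, `group` in {normal, EAC, UPSC}).
#' @export
simulate_probe_cohort <- function(latent, genome, cohort = cohort_config(),
                                  seed = 1L) {
  set.seed(seed)
  w <- latent$windows
  cpg <- genome$cpg
  genome_kb <- sum(genome$chrom_sizes$size) / 1000
  n_probes <- round(cohort$probes_per_kb * genome_kb)
  in_bias <- overlap_count(tibble(chrom = cpg$chrom, start = cpg$pos, end = cpg$pos + 1L),
                           bind_rows(genome$cgis[c("chrom", "start", "end")],
                                     genome$promoters[c("chrom", "start", "end")])) > 0
  weight <- ifelse(in_bias, cohort$cgi_bias, 1)
  pick <- sample.int(nrow(cpg), min(n_probes, nrow(cpg)), prob = weight)
  probes <- tibble(chrom = cpg$chrom[pick], pos = cpg$pos[pick]) |>
    arrange(.data$chrom, .data$pos)
  probes$probe_id <- sprintf("pb%05d", seq_len(nrow(probes)))
  hit <- intervals_to_windows(tibble(chrom = probes$chrom, start = probes$pos,
                                     end = probes$pos + 1L), w)
  probes$win_id <- NA_integer_
  probes$win_id[hit$row] <- hit$win_id

  planted <- latent$truth$win_id[latent$truth$class != "x_block"]
  drop_windows <- sample(planted, round(cohort$zero_probe_frac * length(planted)))
  probes <- probes[!(probes$win_id %in% drop_windows), ]

  groups <- tibble(
    sample = c(sprintf("N%02d", seq_len(cohort$n_normal)),
               sprintf("E%02d", seq_len(cohort$n_eac)),
               sprintf("U%02d", seq_len(cohort$n_upsc))),
    group = rep(c("normal", "EAC", "UPSC"),
                c(cohort$n_normal, cohort$n_eac, cohort$n_upsc))
  )
  gm <- latent$group_m[probes$win_id, c("NE", "EAC", "UPSC"), drop = FALSE]
  colnames(gm) <- c("normal", "EAC", "UPSC")
  beta <- matrix(NA_real_, nrow = nrow(probes), ncol = nrow(groups),
                 dimnames = list(probes$probe_id, groups$sample))
  for (j in seq_len(nrow(groups))) {
    mu <- pmin(pmax(gm[, groups$group[j]], 0.01), 0.99)
    beta[, j] <- rbeta(nrow(probes), mu * cohort$precision, (1 - mu) * cohort$precision)
  }
  if (cohort$missing_rate > 0) {
    beta[runif(length(beta)) < cohort$missing_rate] <- NA_real_
  }
  structure(list(probes = probes, beta = beta, groups = groups,
                 config = cohort),
            class = "beta_cohort")
}
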