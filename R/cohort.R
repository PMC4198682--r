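# Independent-cohort validation of DMRs on a probe-array beta-value matrix:
# quantile normalization, probe coverage, average methylation level (aML),
# methylation change (DMC), Mann-Whitney testing with BH correction, and the
# three-part validation rule.

#' Quantile-normalize a beta-value matrix across samples
#'
#' Each sample's sorted values are mapped to the cross-sample mean quantile
#' profile, with ties averaged; missing values stay missing and are excluded
#' from rank computation.
#'
#' @param beta Numeric matrix (probes x samples), `NA` allowed.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(beta) {
  stopifnot(is.matrix(beta), ncol(beta) >= 2)
  out <- limma::normalizeQuantiles(beta, ties = TRUE)
  dimnames(out) <- dimnames(beta)
  out
}

#' Probe coverage of a DMR set
#'
#' A probe is inside a DMR iff its position lies in `[start, end)`. Reports,
#' per change direction, the fractions of DMRs with 0, >= 1, >= 2 and > 2
#' probes.
#'
#' @param dmrs Tibble with `chrom`, `start`, `end`, `direction`.
#' @param probes Tibble with `chrom`, `pos`.
#' @return A tibble `direction`, `n_dmr`, `f0`, `f1plus`, `f2plus`, `fgt2`.
#' @export
probe_coverage <- function(dmrs, probes) {
  if (nrow(dmrs) == 0) {
    return(tibble(direction = character(), n_dmr = integer(), f0 = numeric(),
                  f1plus = numeric(), f2plus = numeric(), fgt2 = numeric()))
  }
  pr <- tibble(chrom = probes$chrom, start = probes$pos, end = probes$pos + 1L)
  n_probes <- overlap_count(dmrs, pr)
  tibble(direction = dmrs$direction, n_probes = n_probes) |>
    group_by(.data$direction) |>
    summarise(n_dmr = n(),
              f0 = mean(.data$n_probes == 0),
              f1plus = mean(.data$n_probes >= 1),
              f2plus = mean(.data$n_probes >= 2),
              fgt2 = mean(.data$n_probes > 2),
              .groups = "drop")
}

probes_in_dmr <- function(dmr, probes) {
  which(probes$chrom == dmr$chrom & probes$pos >= dmr$start & probes$pos < dmr$end)
}

#' Average methylation level (aML) of a DMR in a sample group
#'
#' The mean over all (sample, probe) beta values in the group x DMR block;
#' missing entries are excluded with the denominator reduced accordingly.
#'
#' @param dmr One-row tibble (`chrom`, `start`, `end`).
#' @param cohort A `beta_cohort` (see [simulate_probe_cohort()]): list with
#'   `probes`, `beta`, `groups`.
#' @param group Group label.
#' @return A single value in `[0, 1]`, or `NA` if the block has no probes or
#'   no non-missing values.
#' @export
aml <- function(dmr, cohort, group) {
  pi <- probes_in_dmr(dmr, cohort$probes)
  if (length(pi) == 0) return(NA_real_)
  si <- which(cohort$groups$group == group)
  if (length(si) == 0) abort(paste0("unknown group label: ", group))
  block <- cohort$beta[pi, si, drop = FALSE]
  if (all(is.na(block))) return(NA_real_)
  mean(block, na.rm = TRUE)
}

#' DNA methylation change (DMC) of a DMR between groups
#'
#' `DMC = aML_cancer - aML_normal`.
#'
#' @inheritParams aml
#' @param cancer_group,normal_group Group labels.
#' @return A value in `[-1, 1]`, or `NA` when either aML is undefined.
#' @export
dmc <- function(dmr, cohort, cancer_group, normal_group = "normal") {
  aml(dmr, cohort, cancer_group) - aml(dmr, cohort, normal_group)
}

#' Two-sided Mann-Whitney U test
#'
#' For small samples (`length(x) + length(y) <= exact_max`) the p-value is
#' computed by full enumeration of all group assignments of the pooled values
#' (valid with ties): p is the fraction of assignments whose U statistic is at
#' least as far from its null mean as the observed one. Larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (length >= 1).
#' @param exact_max Pooled-size bound for exact enumeration (default 12).
#' @return The two-sided p-value.
#' @export
mwu_test <- function(x, y, exact_max = 12L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x)
  n2 <- length(y)
  if (n1 + n2 <= exact_max) {
    pooled <- c(x, y)
    r <- rank(pooled)
    mu <- n1 * n2 / 2
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- utils::combn(n1 + n2, n1)
    u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}

#' Validate DMRs in an independent probe-array cohort
#'
#' For each DMR carrying at least one probe, computes per-sample mean beta
#' values over the DMR's probes, compares cancer vs normal by the Mann-Whitney
#' U test (sample-level values by default, avoiding pseudoreplication; probe
#' pooling available via `unit = "probe"`), adjusts p-values by BH across all
#' testable DMRs of the batch, and applies the three-part rule: a DMR is
#' validated iff `q < q_cutoff`, `|DMC| > dmc_cutoff` and the observed change
#' direction matches the prediction. DMRs without probes (or without
#' non-missing values in a group) are reported untestable and excluded from
#' the BH family.
#'
#' @param dmrs Tibble with `chrom`, `start`, `end` and a `direction` column
#'   holding the predicted change direction.
#' @param cohort A `beta_cohort`.
#' @param cancer_group,normal_group Group labels to compare.
#' @param q_cutoff,dmc_cutoff Validation thresholds (defaults 0.05 and 0.05).
#' @param unit `"sample"` (per-sample probe-mean betas; n = biological
#'   samples) or `"probe"` (pool probe-level betas within group).
#' @return `dmrs` with columns `w` (probes in DMR), `aml_cancer`, `aml_normal`,
#'   `dmc`, `p_value`, `q_value`, `observed_direction`, `testable`,
#'   `validated`.
#' @export
validate_dmrs <- function(dmrs, cohort, cancer_group, normal_group = "normal",
                          q_cutoff = 0.05, dmc_cutoff = 0.05,
                          unit = c("sample", "probe")) {
  unit <- match.arg(unit)
  if (!all(c(cancer_group, normal_group) %in% cohort$groups$group)) {
    abort("unknown group label")
  }
  si_c <- which(cohort$groups$group == cancer_group)
  si_n <- which(cohort$groups$group == normal_group)
  if (nrow(dmrs) == 0) {
    return(mutate(dmrs, w = integer(0), aml_cancer = numeric(0),
                  aml_normal = numeric(0), dmc = numeric(0),
                  p_value = numeric(0), testable = logical(0),
                  q_value = numeric(0), observed_direction = character(0),
                  validated = logical(0)))
  }
  res <- map_dfr(seq_len(nrow(dmrs)), function(i) {
    d <- dmrs[i, ]
    pi <- probes_in_dmr(d, cohort$probes)
    w <- length(pi)
    if (w == 0) {
      return(tibble(w = 0L, aml_cancer = NA_real_, aml_normal = NA_real_,
                    dmc = NA_real_, p_value = NA_real_))
    }
    block_c <- cohort$beta[pi, si_c, drop = FALSE]
    block_n <- cohort$beta[pi, si_n, drop = FALSE]
    aml_c <- if (all(is.na(block_c))) NA_real_ else mean(block_c, na.rm = TRUE)
    aml_n <- if (all(is.na(block_n))) NA_real_ else mean(block_n, na.rm = TRUE)
    if (is.na(aml_c) || is.na(aml_n)) {
      return(tibble(w = w, aml_cancer = aml_c, aml_normal = aml_n,
                    dmc = NA_real_, p_value = NA_real_))
    }
    if (unit == "sample") {
      vc <- colMeans(block_c, na.rm = TRUE)
      vn <- colMeans(block_n, na.rm = TRUE)
    } else {
      vc <- as.vector(block_c)
      vn <- as.vector(block_n)
    }
    vc <- vc[is.finite(vc)]
    vn <- vn[is.finite(vn)]
    p <- if (length(vc) >= 1 && length(vn) >= 1) mwu_test(vc, vn) else NA_real_
    tibble(w = w, aml_cancer = aml_c, aml_normal = aml_n,
           dmc = aml_c - aml_n, p_value = p)
  })
  out <- bind_cols(dmrs, res)
  out$testable <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[out$testable] <- bh_adjust(out$p_value[out$testable])
  out$observed_direction <- case_when(out$dmc > 0 ~ "hyper",
                                      out$dmc < 0 ~ "hypo",
                                      TRUE ~ NA_character_)
  out$validated <- out$testable &
    !is.na(out$q_value) & out$q_value < q_cutoff &
    !is.na(out$dmc) & abs(out$dmc) > dmc_cutoff &
    !is.na(out$observed_direction) & out$observed_direction == out$direction
  out
}
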