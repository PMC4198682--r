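# Windowed differential methylation testing from paired MeDIP/MRE count
# tracks. The per-window statistic conditions each assay's tumor count on the
# pair total (binomial with exposure-determined null proportion), converts the
# mid-p one-sided tail to a signed normal score, and combines the two assays
# by a Stouffer sum with the MRE sign flipped (MRE reads mark UNmethylated
# CpGs, so tumor MRE enrichment is evidence of hypomethylation).

#' Attach normalized exposures to a windowed count track
#'
#' The effective per-window exposure of each assay is
#' `library_total * cnv_factor`; library totals are the per-window count sums.
#' When per-enzyme MRE counts are supplied, each enzyme's counts are first
#' rescaled to equal per-enzyme totals (accounting for enzyme-efficiency
#' differences) and then pooled into the `mre` column. Raw counts are
#' preserved.
#'
#' @param track Tibble with columns `medip`, `mre`, and optionally `cnv`
#'   (default 1).
#' @param mre_by_enzyme Optional matrix or data frame (windows x enzymes) of
#'   per-enzyme MRE counts; when given it replaces `mre` after rescaling.
#' @return The track with columns `cnv`, `medip_exposure`, `mre_exposure`
#'   added (and `mre` replaced if `mre_by_enzyme` was given).
#' @export
normalize_track <- function(track, mre_by_enzyme = NULL) {
  stopifnot(all(c("medip", "mre") %in% names(track)))
  if (!"cnv" %in% names(track)) track$cnv <- 1
  stopifnot(all(track$cnv > 0))
  if (!is.null(mre_by_enzyme)) {
    mre_by_enzyme <- as.matrix(mre_by_enzyme)
    stopifnot(nrow(mre_by_enzyme) == nrow(track))
    totals <- colSums(mre_by_enzyme)
    if (any(totals == 0)) abort("an MRE enzyme has zero total reads")
    scaled <- sweep(mre_by_enzyme, 2, mean(totals) / totals, `*`)
    track$mre <- rowSums(scaled)
  }
  medip_total <- sum(track$medip)
  mre_total <- sum(track$mre)
  if (medip_total <= 0 && mre_total <= 0) abort("zero library total in both assays")
  track$medip_exposure <- medip_total * track$cnv
  track$mre_exposure <- mre_total * track$cnv
  track
}

# signed normal score from the mid-p one-sided tail of Binomial(T, p0) at x.
# Positive = x above its conditional expectation. The score is derived from
# whichever tail is smaller, so swapping the roles of the two samples flips
# the sign exactly (no 1-p cancellation). Zero-information entries (T = 0)
# return 0.
binom_midp_z <- function(x, size, p0) {
  half <- 0.5 * dbinom(x, size, p0)
  p_up <- pbinom(x, size, p0, lower.tail = FALSE) + half
  p_dn <- pbinom(x - 1, size, p0, lower.tail = TRUE) + half
  p_up <- pmax(p_up, 1e-300)
  p_dn <- pmax(p_dn, 1e-300)
  z <- ifelse(p_up <= p_dn,
              qnorm(p_up, lower.tail = FALSE),
              qnorm(p_dn, lower.tail = TRUE))
  z[size == 0] <- 0
  z
}

#' Integrated dual-assay differential methylation test for one window
#'
#' Vectorized over windows. MeDIP evidence: conditional on the pair total
#' `x_n + x_t`, the tumor count is Binomial with null proportion
#' `s_t / (s_n + s_t)`; the mid-p one-sided tail is converted to a signed
#' normal score `z_M` (positive = tumor MeDIP-enriched). MRE evidence `z_R`
#' likewise. The combined statistic is `Z = (z_M - z_R) / sqrt(2)`; if one
#' assay carries no reads in the window pair, `Z` is the other assay's score
#' alone. The two-sided p-value comes from the standard normal; direction is
#' `hyper` for `Z > 0`, `hypo` for `Z < 0`.
#'
#' @param x_n,x_t MeDIP counts in normal and tumor.
#' @param y_n,y_t MRE counts in normal and tumor.
#' @param s_n_medip,s_t_medip,s_n_mre,s_t_mre Per-assay exposures
#'   (library total x CNV factor).
#' @return A tibble with `statistic`, `p_value`, `direction`.
#' @export
window_test <- function(x_n, x_t, y_n, y_t,
                        s_n_medip, s_t_medip, s_n_mre, s_t_mre) {
  t_medip <- x_n + x_t
  t_mre <- y_n + y_t
  p0_medip <- s_t_medip / (s_n_medip + s_t_medip)
  p0_mre <- s_t_mre / (s_n_mre + s_t_mre)
  z_m <- binom_midp_z(x_t, t_medip, p0_medip)
  z_r <- binom_midp_z(y_t, t_mre, p0_mre)
  has_m <- t_medip > 0
  has_r <- t_mre > 0
  z <- ifelse(has_m & has_r, (z_m - z_r) / sqrt(2),
              ifelse(has_m, z_m, ifelse(has_r, -z_r, 0)))
  p <- ifelse(!has_m & !has_r, 1, pmin(2 * pnorm(-abs(z)), 1))
  tibble(statistic = z, p_value = p,
         direction = case_when(z > 0 ~ "hyper", z < 0 ~ "hypo",
                               TRUE ~ NA_character_))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement; order-preserving with respect to
#' the input p-values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Call per-window DMRs for one tumor-vs-normal pair
#'
#' Windows without CpGs are excluded before testing and before multiple-test
#' correction (both assays are CpG-conditional, so such windows carry no
#' information). BH is applied over all tested windows of the comparison;
#' calls are windows with `q < q_cutoff`.
#'
#' @param normal,tumor Track tibbles sharing an identical window frame
#'   (columns `win_id`, `cpg_count`, `medip`, `mre`, optional `cnv`).
#' @param q_cutoff Significance cutoff on the BH-adjusted p-value
#'   (default 1e-5).
#' @return A tibble of calls: window frame columns plus `statistic`,
#'   `p_value`, `q_value`, `direction`.
#' @export
call_pairwise_dmrs <- function(normal, tumor, q_cutoff = 1e-5) {
  if (!identical(normal$win_id, tumor$win_id) ||
      !identical(normal$start, tumor$start) ||
      !identical(normal$chrom, tumor$chrom)) {
    abort("normal and tumor tracks must share an identical window frame")
  }
  normal <- normalize_track(normal)
  tumor <- normalize_track(tumor)
  keep <- normal$cpg_count >= 1
  nt <- normal[keep, ]
  tt <- tumor[keep, ]
  res <- window_test(nt$medip, tt$medip, nt$mre, tt$mre,
                     nt$medip_exposure, tt$medip_exposure,
                     nt$mre_exposure, tt$mre_exposure)
  res$q_value <- bh_adjust(res$p_value)
  out <- bind_cols(nt[intersect(c("chrom", "start", "end", "win_id", "cpg_count"),
                                names(nt))], res)
  out[out$q_value < q_cutoff & !is.na(out$direction), ]
}
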