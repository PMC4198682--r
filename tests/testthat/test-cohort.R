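make_cohort <- function(beta, positions, groups) {
  probes <- tibble::tibble(probe_id = rownames(beta), chrom = "chr1",
                           pos = positions, win_id = NA_integer_)
  list(probes = probes, beta = beta, groups = groups)
}

test_that("quantile normalization maps samples onto the mean quantile profile", {
  # hand-computed no-tie case
  b <- cbind(s1 = c(0.1, 0.5, 0.9), s2 = c(0.2, 0.4, 0.6))
  got <- quantile_normalize(b)
  expect_equal(unname(got[, 1]), c(0.15, 0.45, 0.75))
  expect_equal(unname(got[, 2]), c(0.15, 0.45, 0.75))

  # identical samples are unchanged
  b2 <- cbind(a = c(0.3, 0.1, 0.8), b = c(0.3, 0.1, 0.8))
  expect_equal(quantile_normalize(b2), b2)

  # complete samples share column means after normalization
  set.seed(20)
  b3 <- matrix(runif(60), 15, 4)
  got3 <- quantile_normalize(b3)
  expect_equal(diff(range(colMeans(got3))), 0, tolerance = 1e-12)
})

test_that("probe coverage bins DMRs by probe count per direction", {
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = c(0L, 1000L, 2000L),
                         end = c(500L, 1500L, 2500L),
                         direction = c("hyper", "hyper", "hypo"))
  probes <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L, 1499L))
  cov <- probe_coverage(dmrs, probes)
  hyper <- cov[cov$direction == "hyper", ]
  expect_equal(hyper$f0, 0)
  expect_equal(hyper$f1plus, 1)
  expect_equal(hyper$f2plus, 0.5)
  expect_equal(hyper$fgt2, 0.5)   # 3 probes in the first DMR
  hypo <- cov[cov$direction == "hypo", ]
  expect_equal(hypo$f0, 1)
  expect_equal(hypo$f0 + hypo$f1plus, 1)
  # boundary: a probe at `end` is outside the half-open DMR
  expect_equal(probe_coverage(dmrs[1, ],
                              tibble::tibble(chrom = "chr1", pos = 500L))$f0, 1)
})

test_that("aML and DMC follow their block-mean definitions", {
  beta <- matrix(c(0.7, 0.2, 0.6, 0.4, 0.8, NA), nrow = 2,
                 dimnames = list(c("p1", "p2"), c("n1", "c1", "c2")))
  groups <- tibble::tibble(sample = c("n1", "c1", "c2"),
                           group = c("normal", "cancer", "cancer"))
  co <- make_cohort(beta, positions = c(100L, 200L), groups = groups)
  dmr <- tibble::tibble(chrom = "chr1", start = 0L, end = 300L)

  expect_equal(aml(dmr, co, "normal"), mean(c(0.7, 0.2)))
  expect_equal(aml(dmr, co, "cancer"), mean(c(0.6, 0.4, 0.8)))  # NA excluded
  expect_equal(dmc(dmr, co, "cancer"), mean(c(0.6, 0.4, 0.8)) - 0.45)

  # single probe, single sample
  dmr1 <- tibble::tibble(chrom = "chr1", start = 0L, end = 150L)
  expect_equal(aml(dmr1, co, "normal"), 0.7)

  # 2 probes x 2 samples block with betas {0.2,0.4,0.6,0.8} averages to 0.5
  beta2 <- matrix(c(0.2, 0.4, 0.6, 0.8), nrow = 2,
                  dimnames = list(c("p1", "p2"), c("c1", "c2")))
  co2 <- make_cohort(beta2, c(100L, 200L),
                     tibble::tibble(sample = c("c1", "c2"),
                                    group = c("cancer", "cancer")))
  expect_equal(aml(dmr, co2, "cancer"), 0.5)

  # all-missing block is undefined
  beta3 <- matrix(NA_real_, 1, 2, dimnames = list("p1", c("a", "b")))
  co3 <- make_cohort(beta3, 100L,
                     tibble::tibble(sample = c("a", "b"),
                                    group = c("normal", "cancer")))
  expect_true(is.na(aml(dmr, co3, "normal")))
  expect_error(aml(dmr, co, "nope"), "unknown group")
})

test_that("exact Mann-Whitney matches enumeration, ties included", {
  expect_equal(mwu_test(1:3, 4:6), 0.1)          # U = 0, 2/20 arrangements
  expect_equal(mwu_test(c(1, 2), c(1, 2)), 1)    # identical sets
  # against enumeration over random small splits, with and without ties
  set.seed(30)
  for (i in 1:60) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    vals <- if (i %% 2 == 0) sample(1:4, n1 + n2, replace = TRUE) else rnorm(n1 + n2)
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    expect_equal(mwu_test(x, y), mwu_enum_oracle(x, y))
  }
  # tie-free exact p agrees with the distribution-based reference
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(4)
    y <- rnorm(5)
    expect_equal(mwu_test(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # large samples fall back to the tie-corrected normal approximation
  set.seed(32)
  x <- rnorm(30); y <- rnorm(30) + 0.5
  expect_equal(mwu_test(x, y),
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
})

test_that("validation applies the three-part rule", {
  # 6 + 6 samples, one strong DMR, one null DMR, one probe-free DMR,
  # one DMR with real significance but negligible effect size
  set.seed(40)
  n <- 6
  groups <- tibble::tibble(sample = c(paste0("n", 1:n), paste0("c", 1:n)),
                           group = rep(c("normal", "cancer"), each = n))
  pos <- c(100L, 150L, 1100L, 2100L)
  beta <- rbind(
    strong1 = c(rnorm(n, 0.2, 0.01), rnorm(n, 0.8, 0.01)),
    strong2 = c(rnorm(n, 0.2, 0.01), rnorm(n, 0.8, 0.01)),
    null1 = rep(0.5, 2 * n),
    small = c(rnorm(n, 0.50, 0.001), rnorm(n, 0.54, 0.001))
  )
  colnames(beta) <- groups$sample
  co <- make_cohort(pmin(pmax(beta, 0), 1), pos, groups)
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = c(0L, 1000L, 2000L, 3000L),
                         end = c(500L, 1500L, 2500L, 3500L),
                         direction = c("hyper", "hyper", "hyper", "hyper"))
  rec <- validate_dmrs(dmrs, co, cancer_group = "cancer")
  expect_equal(rec$w, c(2L, 1L, 1L, 0L))
  expect_true(rec$validated[1])
  expect_false(rec$validated[2])          # no group difference
  expect_false(rec$validated[4])          # untestable, no probes
  expect_false(rec$testable[4])
  # |DMC| = 0.04 < 0.05 fails criterion 2 even when q is tiny
  expect_lt(rec$q_value[3], 0.05)
  expect_lt(abs(rec$dmc[3]), 0.05)
  expect_false(rec$validated[3])

  # direction mismatch fails criterion 3
  dmrs_flip <- dplyr::mutate(dmrs[1, ], direction = "hypo")
  expect_false(validate_dmrs(dmrs_flip, co, cancer_group = "cancer")$validated)

  # invariance to sample and probe order
  perm_s <- sample(ncol(co$beta))
  perm_p <- sample(nrow(co$beta))
  co_perm <- make_cohort(co$beta[perm_p, perm_s], pos[perm_p],
                         groups[perm_s, ])
  rec2 <- validate_dmrs(dmrs, co_perm, cancer_group = "cancer")
  expect_equal(rec2$p_value, rec$p_value)
  expect_equal(rec2$dmc, rec$dmc)
  expect_error(validate_dmrs(dmrs, co, cancer_group = "missing"), "unknown group")
})

test_that("aML of a merged group is the weighted mean of subgroup aMLs", {
  set.seed(41)
  beta <- matrix(runif(40), nrow = 4,
                 dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  groups <- tibble::tibble(sample = paste0("s", 1:10),
                           group = c(rep("g1", 4), rep("g2", 6)))
  co <- make_cohort(beta, c(10L, 20L, 30L, 40L), groups)
  dmr <- tibble::tibble(chrom = "chr1", start = 0L, end = 50L)
  co_merged <- co
  co_merged$groups$group <- "all"
  w1 <- 4 * 4; w2 <- 4 * 6
  expect_equal(aml(dmr, co_merged, "all"),
               (w1 * aml(dmr, co, "g1") + w2 * aml(dmr, co, "g2")) / (w1 + w2))
})

test_that("planted cohort validates and the null cohort does not", {
  g <- generate_genome(seed = 50)
  lat <- plant_methylomes(g, methylome_design(), seed = 51)
  co <- simulate_probe_cohort(lat, g, cohort_config(), seed = 52)
  planted <- lat$truth[lat$truth$class == "shared", ]
  w <- lat$windows
  dmrs <- tibble::tibble(chrom = w$chrom[planted$win_id],
                         start = w$start[planted$win_id],
                         end = w$end[planted$win_id],
                         direction = planted$direction)
  rec <- validate_dmrs(dmrs, co, cancer_group = "EAC")
  expect_gte(mean(rec$validated[rec$testable]), 0.9)

  # null: identical latent levels across groups
  lat0 <- plant_methylomes(g, methylome_design(n_eac = 0L, n_upsc = 0L,
                                               n_shared = 0L, x_block_delta = 0,
                                               jitter_sd = 0, cnv_blocks = 0L),
                           seed = 53)
  co0 <- simulate_probe_cohort(lat0, g, cohort_config(zero_probe_frac = 0),
                               seed = 54)
  rec0 <- validate_dmrs(dmrs, co0, cancer_group = "EAC")
  expect_lte(mean(rec0$validated[rec0$testable]), 0.05 + 0.05)
})
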