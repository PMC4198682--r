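toy_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- feature_catalog(generate_genome(seed = 31))
    cache
  }
})

test_that("shores flank islands without overlapping any island body", {
  cat <- toy_catalog()
  expect_equal(nrow(overlap_join(cat$shores, cat$cgis)), 0)
  # each island contributes flanks adjacent to its body
  one <- cat$cgis[1, ]
  sh <- cat$shores[cat$shores$cgi_id == one$cgi_id, ]
  expect_true(any(sh$end == one$start) || any(sh$start == one$end))
})

test_that("exclusive context uses promoter > exon > intron > intergenic priority", {
  cat <- toy_catalog()
  # a DMR overlapping a promoter wins regardless of other overlaps
  prom_dmr <- cat$promoters[1, c("chrom", "start", "end")]
  got <- classify_context(prom_dmr, cat)
  expect_equal(got$context, "promoter")

  # an intronic interval away from promoters/exons is labeled intron
  big <- cat$introns[cat$introns$end - cat$introns$start > 2000, ]
  mids <- tibble::tibble(chrom = big$chrom,
                         start = (big$start + big$end) %/% 2L,
                         end = (big$start + big$end) %/% 2L + 100L)
  clean <- mids[overlap_count(mids, cat$promoters) == 0 &
                  overlap_count(mids, cat$exons) == 0, ]
  expect_gt(nrow(clean), 0)
  expect_true(all(classify_context(clean, cat)$context == "intron"))

  # an interval overlapping nothing is intergenic with no flags
  ig <- cat$intergenic[which(cat$intergenic$end - cat$intergenic$start > 5000)[1], ]
  mid <- floor((ig$start + ig$end) / 2)
  naked <- tibble::tibble(chrom = ig$chrom, start = mid, end = mid + 50L)
  got2 <- classify_context(naked, cat)
  expect_equal(got2$context, "intergenic")

  # shore flag without CGI flag for a DMR inside a flank only
  sh <- cat$shores[cat$shores$end - cat$shores$start >= 400, ][1, ]
  mid <- floor((sh$start + sh$end) / 2)
  sh_dmr <- tibble::tibble(chrom = sh$chrom, start = mid - 50L, end = mid + 50L)
  got3 <- classify_context(sh_dmr, cat)
  expect_true(got3$in_shore)
  expect_false(got3$in_cgi)
})

test_that("enrichment score matches its formula and the brute-force oracle", {
  # direct formula case: half the DMRs carry a feature present in 1/10 of
  # genome windows -> ES = 5
  w <- make_windows(c(chrA = 10000), width = 100)  # 100 windows
  feat <- w[1:10, c("chrom", "start", "end")]
  dmrs <- w[c(1:5, 11:15), c("chrom", "start", "end")]
  res <- feature_enrichment(dmrs, list(f = feat), w)
  expect_equal(res$es, (5 / 10) / (10 / 100))
  expect_equal(res$n_hit, 5L)

  # a feature at the genome rate gives ES = 1; the all-windows pseudo-feature
  # gives ES exactly 1
  res2 <- feature_enrichment(w[1:20, ], list(all = w[, c("chrom", "start", "end")]), w)
  expect_equal(res2$es, 1)

  # random configurations against independent recomputation from raw overlaps
  set.seed(77)
  for (i in 1:20) {
    nw <- sample(50:200, 1)
    w <- make_windows(c(chrA = nw * 100L), width = 100)
    feat <- random_intervals(sample(5:30, 1), chroms = "chrA", max_pos = nw * 100L)
    dmrs <- w[sample(nw, sample(5:20, 1)), c("chrom", "start", "end")]
    res <- feature_enrichment(dmrs, list(f = feat), w)
    n_hit <- sum(vapply(seq_len(nrow(dmrs)), function(q) {
      any(feat$start < dmrs$end[q] & feat$end > dmrs$start[q])
    }, logical(1)))
    N_hit <- sum(vapply(seq_len(nrow(w)), function(q) {
      any(feat$start < w$end[q] & feat$end > w$start[q])
    }, logical(1)))
    if (N_hit == 0) {
      expect_true(is.na(res$es))
    } else {
      expect_equal(res$es, (n_hit / nrow(dmrs)) / (N_hit / nrow(w)))
    }
  }
})

test_that("island/shore patterns split by body and flank hits per direction", {
  cgis <- tibble::tibble(chrom = "chr1", start = c(5000L, 20000L, 40000L),
                         end = c(6000L, 21000L, 41000L),
                         cgi_id = c("a", "b", "c"))
  genome <- list(cgis = cgis,
                 chrom_sizes = tibble::tibble(chrom = "chr1", size = 50000L),
                 genes = tibble::tibble(chrom = character(), start = integer(),
                                        end = integer(), gene_id = character()),
                 exons = tibble::tibble(chrom = character(), start = integer(),
                                        end = integer()),
                 promoters = tibble::tibble(chrom = character(), start = integer(),
                                            end = integer()),
                 te = tibble::tibble(chrom = character(), start = integer(),
                                     end = integer(), subfamily = character()),
                 windows = make_windows(c(chr1 = 50000L), 500L))
  cat <- feature_catalog(genome)
  dmrs <- tibble::tibble(
    chrom = "chr1",
    start = c(5200L, 19500L, 20100L, 41200L),
    end = c(5700L, 20000L, 20600L, 41700L),
    direction = c("hyper", "hyper", "hyper", "hyper")
  )
  pat <- cgi_shore_patterns(cat, dmrs)
  hyper <- pat[pat$direction == "hyper", ]
  expect_equal(hyper$category[hyper$cgi_id == "a"], "CGI-only")
  expect_equal(hyper$category[hyper$cgi_id == "b"], "CGI+shore")
  expect_equal(hyper$category[hyper$cgi_id == "c"], "shore-only")
  hypo <- pat[pat$direction == "hypo", ]
  expect_true(all(hypo$category == "none"))
})

test_that("dominant state requires strictly more than half the window", {
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L, win_id = 1L)
  seg3 <- tibble::tibble(chrom = "chr1", start = c(0L, 300L),
                         end = c(300L, 500L), state = c("Enh", "Txn"))
  expect_equal(dominant_state(w, seg3)$state, "Enh")
  tie <- tibble::tibble(chrom = "chr1", start = c(0L, 250L),
                        end = c(250L, 500L), state = c("Enh", "Txn"))
  expect_true(is.na(dominant_state(w, tie)$state))
  full <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L, state = "Tss")
  expect_equal(dominant_state(w, full)$state, "Tss")
})

test_that("state merging gives promoter precedence over enhancer", {
  ds <- tibble::tibble(win_id = c(1L, 1L, 2L, 2L, 3L, 3L),
                       state = c("Tss", "Enh", "Enh", "Txn", "Txn", NA),
                       cell_line = rep(c("c1", "c2"), 3))
  got <- merge_states(ds)
  expect_equal(got$reg_class, c("promoter", "enhancer", "other"))
  expect_error(merge_states(tibble::tibble(win_id = 1L, state = "Weird",
                                           cell_line = "c1")), "Weird")
})

test_that("merged labels never call enhancer where any line is promoter", {
  set.seed(99)
  states <- c("Tss", "Enh", "Txn", NA)
  ds <- tibble::tibble(win_id = rep(1:200, each = 3),
                       state = sample(states, 600, replace = TRUE),
                       cell_line = rep(c("c1", "c2", "c3"), 200))
  got <- merge_states(ds)
  prom_windows <- unique(ds$win_id[!is.na(ds$state) & ds$state == "Tss"])
  expect_false(any(got$reg_class[got$win_id %in% prom_windows] == "enhancer"))
  enh_rows <- got$win_id[got$reg_class == "enhancer"]
  expect_true(all(enh_rows %in% ds$win_id[!is.na(ds$state) & ds$state == "Enh"]))
})

test_that("developmental pattern mapping follows the four three-state words", {
  expect_equal(methylation_pattern("hypo", "none"), "MMU")
  expect_equal(methylation_pattern("hyper", "NE-lower"), "MUM")
  expect_equal(methylation_pattern("hypo", "NE-higher"), "UMU")
  expect_equal(methylation_pattern("hyper", "none"), "UUM")
  expect_true(is.na(methylation_pattern("hyper", "NE-higher")))
})

test_that("TE report reproduces overlap fractions and flags planted subfamilies", {
  te <- tibble::tibble(chrom = "chr1",
                       start = seq(0L, 19000L, by = 1000L),
                       end = seq(0L, 19000L, by = 1000L) + 400L,
                       subfamily = rep(c("LTR6A", "AluYa5"), 10))
  w <- make_windows(c(chr1 = 100000L), 500L)
  # hyper DMRs planted inside every LTR6A copy; hypo DMRs elsewhere
  ltr <- te[te$subfamily == "LTR6A", ]
  dmrs <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = ltr$start, end = ltr$start + 300L,
                   direction = "hyper"),
    tibble::tibble(chrom = "chr1", start = seq(50000L, 59000L, by = 1000L),
                   end = seq(50000L, 59000L, by = 1000L) + 300L,
                   direction = "hypo")
  )
  rep <- te_enrichment_report(dmrs, te, w)
  ov <- rep$overall
  expect_equal(ov$frac_te[ov$direction == "hyper"], 1)
  expect_equal(ov$frac_te[ov$direction == "hypo"], 0)
  sub <- rep$by_subfamily
  ltr_hyper <- sub[sub$direction == "hyper" & sub$subfamily == "LTR6A", ]
  expect_gt(ltr_hyper$es, 5)
  expect_true(ltr_hyper$flag_5fold)
  # brute-force overlap fraction oracle
  brute_frac <- mean(vapply(which(dmrs$direction == "hyper"), function(i) {
    any(te$start < dmrs$end[i] & te$end > dmrs$start[i])
  }, logical(1)))
  expect_equal(ov$frac_te[ov$direction == "hyper"], brute_frac)
})

test_that("binned RPKM follows count/(kb * millions) and planted block signs", {
  # 100 reads in one 500 kb bin of a library with 10M reads -> RPKM 0.02
  w <- make_windows(c(chr1 = 1e6), 500L)
  medip <- integer(nrow(w))
  medip[1] <- 100L
  medip[1500] <- 1e7 - 100L
  tr <- dplyr::mutate(w, medip = medip, mre = 1L)
  prof <- binned_rpkm_profile(list(a = tr), reference = "a", bin_width = 5e5)
  got <- prof$rpkm[prof$rpkm$assay == "medip" & prof$rpkm$bin_start == 0, ]
  expect_equal(got$rpkm, 100 / (500 * 10))

  # identical tracks give log2 fold change 0 everywhere
  prof2 <- binned_rpkm_profile(list(a = tr, b = tr), reference = "a",
                               type_map = c(b = "T"), bin_width = 5e5)
  expect_true(all(prof2$log2fc$log2fc == 0))

  # planted X-like block: MeDIP drops, MRE rises in UPSC
  p <- small_pipeline()
  blk <- p$latent$truth[p$latent$truth$class == "x_block", ]
  w <- p$latent$windows
  blk_range <- range(w$start[w$win_id %in% blk$win_id])
  fc <- p$profile$log2fc
  xc <- p$genome$x_like_chrom
  in_block <- fc$chrom == xc & fc$bin_start >= blk_range[1] & fc$bin_end <= blk_range[2]
  upsc <- fc[in_block & fc$type == "UPSC", ]
  expect_lt(mean(upsc$log2fc[upsc$assay == "medip"], na.rm = TRUE), 0)
  expect_gt(mean(upsc$log2fc[upsc$assay == "mre"], na.rm = TRUE), 0)
})

test_that("global density shift labels bins by fold change", {
  w <- make_windows(c(chr1 = 1e5), 500L)
  set.seed(8)
  normal <- dplyr::mutate(w, medip = rpois(nrow(w), 50), mre = 0L)
  expect_equal(
    global_density_shift(list(t = normal), normal, c(t = "T"))$per_sample$frac_hypo, 0)
  expect_equal(
    global_density_shift(list(t = normal), normal, c(t = "T"))$per_sample$frac_hyper, 0)
  doubled <- dplyr::mutate(normal, medip = medip * 2L)
  res <- global_density_shift(list(t = doubled), normal, c(t = "T"),
                              normalize = FALSE)
  expect_equal(res$per_sample$frac_hyper, 1)
  # after library normalization a uniform doubling is no shift at all
  res2 <- global_density_shift(list(t = doubled), normal, c(t = "T"))
  expect_equal(res2$per_sample$frac_hyper, 0)

  # a deep planted hypomethylation block dominates the labeled fractions
  g <- generate_genome(seed = 71)
  lat <- plant_methylomes(g, methylome_design(n_eac = 0L, n_upsc = 0L,
                                              n_shared = 0L,
                                              x_block_delta = 0.6,
                                              cnv_blocks = 0L),
                          seed = 72)
  tr <- simulate_counts(lat, depth_config(30, 30), seed = 73)
  res3 <- global_density_shift(tr[c("UPSC1", "UPSC2", "UPSC3")], tr$NE,
                               c(UPSC1 = "UPSC", UPSC2 = "UPSC", UPSC3 = "UPSC"))
  per_type <- res3$per_type
  expect_gt(per_type$frac_hypo, per_type$frac_hyper)
  expect_gt(per_type$frac_hypo, 0.05)
})
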