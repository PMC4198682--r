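# Shared fixtures and independent oracles used across test files.

# brute-force O(n*m) interval overlap oracle (half-open)
brute_overlap <- function(queries, subjects) {
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(queries))) {
    for (j in seq_len(nrow(subjects))) {
      if (queries$chrom[i] == subjects$chrom[j]) {
        ov <- min(queries$end[i], subjects$end[j]) -
          max(queries$start[i], subjects$start[j])
        if (ov > 0) {
          k <- k + 1L
          out[[k]] <- c(i, j, ov)
        }
      }
    }
  }
  if (k == 0) {
    return(tibble::tibble(query = integer(), subject = integer(),
                          overlap = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(query = m[, 1], subject = m[, 2], overlap = m[, 3])
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000L) {
  start <- sample.int(max_pos - 100L, n, replace = TRUE) - 1L
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(200L, n, replace = TRUE))
}

# minimal window frame + two tracks with given per-window counts
toy_track <- function(medip, mre, cpg = NULL, mre_sites = NULL, cnv = NULL,
                      width = 500L) {
  n <- length(medip)
  if (is.null(cpg)) cpg <- rep(10L, n)
  if (is.null(mre_sites)) mre_sites <- rep(3L, n)
  if (is.null(cnv)) cnv <- rep(1, n)
  tibble::tibble(chrom = "chr1", start = (seq_len(n) - 1L) * width,
                 end = seq_len(n) * width, win_id = seq_len(n),
                 cpg_count = as.integer(cpg),
                 mre_site_count = as.integer(mre_sites),
                 medip = as.integer(medip), mre = as.integer(mre), cnv = cnv)
}

# small deterministic pipeline objects shared across test files (built once)
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- methdual::run_pipeline(
      methdual::pipeline_config(seed = 7L))
    cache
  }
})

# pairwise-call fixture: windows 1..n with per-comparison directions given as
# a character vector like c("hyper","none","hypo")
calls_from_directions <- function(dirs, win_id = 1L) {
  lapply(dirs, function(d) {
    if (d == "none") {
      tibble::tibble(win_id = integer(), direction = character())
    } else {
      tibble::tibble(win_id = win_id, direction = d)
    }
  })
}

# Independent oracle for the consensus rules, applied to one window given the
# per-comparison directions of both types ("hyper"/"hypo"/"none").
consensus_oracle <- function(dirs, min_support = 2L) {
  nh <- sum(dirs == "hyper")
  nl <- sum(dirs == "hypo")
  if (nh == nl) return(NA_character_)
  maj <- if (nh > nl) "hyper" else "hypo"
  if (max(nh, nl) >= min_support) maj else NA_character_
}


# independent two-sided Mann-Whitney oracle: enumerate every assignment of the
# pooled values to the two groups and count assignments at least as extreme
mwu_enum_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  mu <- n1 * (n - n1) / 2
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(vapply(xs, function(v) sum(v > ys) + 0.5 * sum(v == ys), numeric(1)))
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n, n1)
  u_all <- apply(combs, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

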