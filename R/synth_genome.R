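# Synthetic toy genome: chromosomes, CpG landscape, gene models, CpG islands,
# transposable-element catalog. Everything is deterministic given a seed.

#' Configuration for the toy genome generator
#'
#' Defaults give 2 chromosomes of 2 Mb each (the second is "X-like" and hosts
#' the large hypomethylated block), ~45,000 CpGs placed by a two-rate process
#' (10x the background rate inside CpG islands), ~25% of CpGs flagged as
#' MRE-assayable sites, 40 CpG islands and 60 genes per chromosome, and a
#' transposable-element catalog of 5 subfamilies.
#'
#' @param n_chrom Number of chromosomes (>= 1). The last one is X-like.
#' @param chrom_length Length of each chromosome in bases.
#' @param window_width Analysis window width in bases.
#' @param n_cgi_per_chrom CpG islands per chromosome.
#' @param cgi_width_range Min/max CpG island width in bases.
#' @param cpg_rate_bg Background CpG rate per base (mean over the genome).
#' @param cpg_cluster_size Mean CpGs per background cluster (background CpGs
#'   arrive in clusters, not uniformly: cluster centers follow a Poisson
#'   process, cluster sizes are geometric with this mean, and members spread
#'   around the center with `cpg_cluster_sd`).
#' @param cpg_cluster_sd Gaussian spread (bases) of CpGs around their cluster
#'   center.
#' @param cgi_rate_mult Fold elevation of the CpG rate inside islands.
#' @param mre_fraction Fraction of CpGs that are MRE-assayable sites.
#' @param n_genes_per_chrom Gene models per chromosome.
#' @param gene_length_range Min/max gene-body length in bases.
#' @param n_mirna_tss,n_lnc_tss Extra miRNA-like / lncRNA-like TSS per
#'   chromosome (generic TSS lists, no gene bodies).
#' @param te_catalog Tibble describing TE subfamilies: `subfamily`, `family`,
#'   `class`, `copies` (per genome), `width`, `enhancer_like` (whether the
#'   chromatin-state simulator paints enhancer states on its copies).
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(n_chrom = 2L,
                          chrom_length = 2e6,
                          window_width = 500L,
                          n_cgi_per_chrom = 40L,
                          cgi_width_range = c(600L, 1500L),
                          cpg_rate_bg = 0.01,
                          cpg_cluster_size = 5,
                          cpg_cluster_sd = 60,
                          cgi_rate_mult = 10,
                          mre_fraction = 0.25,
                          n_genes_per_chrom = 60L,
                          gene_length_range = c(4000L, 30000L),
                          n_mirna_tss = 15L,
                          n_lnc_tss = 15L,
                          te_catalog = default_te_catalog()) {
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_length = as.integer(chrom_length),
              window_width = as.integer(window_width),
              n_cgi_per_chrom = as.integer(n_cgi_per_chrom),
              cgi_width_range = as.integer(cgi_width_range),
              cpg_rate_bg = cpg_rate_bg,
              cpg_cluster_size = cpg_cluster_size, cpg_cluster_sd = cpg_cluster_sd,
              cgi_rate_mult = cgi_rate_mult,
              mre_fraction = mre_fraction,
              n_genes_per_chrom = as.integer(n_genes_per_chrom),
              gene_length_range = as.integer(gene_length_range),
              n_mirna_tss = as.integer(n_mirna_tss), n_lnc_tss = as.integer(n_lnc_tss),
              te_catalog = te_catalog)
  structure(cfg, class = "genome_config")
}

#' @rdname genome_config
#' @export
default_te_catalog <- function() {
  tibble(
    subfamily = c("LTR6A", "MER52A", "L1PA3", "AluYa5", "MER41B"),
    family = c("ERV1", "ERV1", "L1", "Alu", "ERV1"),
    class = c("LTR", "LTR", "LINE", "SINE", "LTR"),
    copies = c(40L, 40L, 60L, 80L, 40L),
    width = c(450L, 600L, 900L, 300L, 500L),
    enhancer_like = c(TRUE, TRUE, FALSE, FALSE, TRUE)
  )
}

# Sample n non-overlapping intervals of the given widths on [0, len),
# avoiding `occupied` (tibble with start/end) when supplied.
place_nonoverlapping <- function(len, widths, occupied = NULL, max_tries = 5000L) {
  taken <- if (is.null(occupied) || nrow(occupied) == 0) {
    tibble(start = integer(), end = integer())
  } else {
    tibble(start = occupied$start, end = occupied$end)
  }
  out_start <- integer(0)
  out_end <- integer(0)
  for (w in widths) {
    placed <- FALSE
    for (i in seq_len(max_tries)) {
      s <- sample.int(len - w, 1L) - 1L
      e <- s + w
      clash <- any(s < taken$end & e > taken$start) ||
        any(s < out_end & e > out_start)
    if (!clash) {
        out_start <- c(out_start, s)
        out_end <- c(out_end, e)
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("could not place annotations: configuration exceeds chromosome capacity")
  }
  # returned in placement order so callers can pair rows with `widths`
  tibble(start = out_start, end = out_end)
}

#' Generate a deterministic toy genome
#'
#' Builds chromosomes, CpG islands, gene models with 1 kb core promoters
#' (TSS - 500 to TSS + 500), exons/introns, generic miRNA-like and lncRNA-like
#' TSS lists, a transposable-element catalog, and a CpG landscape placed by a
#' two-rate process (elevated inside islands). About `mre_fraction` of CpGs are
#' flagged as MRE sites. The per-window CpG and MRE-site counts of the 500 bp
#' analysis frame are precomputed.
#'
#' @param config A [genome_config()].
#' @param seed Integer seed; the output is byte-identical for equal seeds.
#' @return A list of class `toy_genome` with elements `chrom_sizes`, `windows`,
#'   `cpg` (tibble `chrom`, `pos`, `is_mre`), `cgis`, `genes`, `exons`,
#'   `promoters`, `tss` (tibble with `class`), `te`, `x_like_chrom`, `config`.
#' @export
generate_genome <- function(config = genome_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  chroms <- if (cfg$n_chrom == 1) "chr1" else
    c(paste0("chr", seq_len(cfg$n_chrom - 1L)), "chrX")
  chrom_sizes <- tibble(chrom = chroms, size = rep(cfg$chrom_length, cfg$n_chrom))
  total_ann <- cfg$n_cgi_per_chrom * mean(cfg$cgi_width_range) +
    cfg$n_genes_per_chrom * mean(cfg$gene_length_range)
  if (total_ann > 0.9 * cfg$chrom_length) {
    abort("infeasible genome config: annotations exceed chromosome length")
  }

  per_chrom <- map(chroms, function(ch) {
    # gene bodies first (largest), then islands inside/outside, then TEs
    gene_w <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2], by = 100L),
                     cfg$n_genes_per_chrom, replace = TRUE)
    genes <- arrange(place_nonoverlapping(cfg$chrom_length, gene_w), .data$start)
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$gene_id <- paste0(ch, "_g", seq_len(nrow(genes)))

    cgi_w <- sample(seq(cfg$cgi_width_range[1], cfg$cgi_width_range[2], by = 50L),
                    cfg$n_cgi_per_chrom, replace = TRUE)
    cgis <- arrange(place_nonoverlapping(cfg$chrom_length, cgi_w), .data$start)
    cgis$cgi_id <- paste0(ch, "_cgi", seq_len(nrow(cgis)))

    te_cat <- cfg$te_catalog
    te_w <- rep(te_cat$width, te_cat$copies %/% cfg$n_chrom)
    te_sub <- rep(te_cat$subfamily, te_cat$copies %/% cfg$n_chrom)
    tes2 <- place_nonoverlapping(cfg$chrom_length, te_w, occupied = cgis)
    tes2$subfamily <- te_sub
    tes2 <- arrange(tes2, .data$start)

    # CpG landscape: clustered background process + extra density inside CGIs.
    # Cluster centers are Poisson; sizes geometric with mean cpg_cluster_size;
    # members spread normally around the center. Mean rate = cpg_rate_bg.
    n_clusters <- rpois(1, cfg$chrom_length * cfg$cpg_rate_bg / cfg$cpg_cluster_size)
    centers <- sample.int(cfg$chrom_length, n_clusters) - 1L
    sizes <- 1L + stats::rgeom(n_clusters, 1 / cfg$cpg_cluster_size)
    pos_bg <- round(rep(centers, sizes) +
                      rnorm(sum(sizes), 0, cfg$cpg_cluster_sd))
    pos_bg <- pos_bg[pos_bg >= 0 & pos_bg < cfg$chrom_length]
    extra <- map2(cgis$start, cgis$end, function(s, e) {
      n <- rpois(1, (e - s) * cfg$cpg_rate_bg * (cfg$cgi_rate_mult - 1))
      sample.int(e - s, min(n, e - s)) - 1L + s
    })
    pos <- sort(unique(c(pos_bg, unlist(extra))))

    list(genes = genes, cgis = cgis, te = tes2, cpg_pos = pos)
  })
  names(per_chrom) <- chroms

  genes <- map_dfr(chroms, function(ch) {
    g <- per_chrom[[ch]]$genes
    tibble(chrom = ch, start = g$start, end = g$end, strand = g$strand,
           gene_id = g$gene_id)
  })
  # exons: 2-4 exons per gene: first/last anchored at gene ends
  exons <- map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    n_ex <- sample(2:4, 1)
    len <- g$end - g$start
    ex_w <- pmin(pmax(round(stats::rgamma(n_ex, 2, rate = 2 / 300)), 80L), len %/% (2L * n_ex))
    anchors <- sort(sample.int(len - max(ex_w), n_ex))
    s <- g$start + anchors
    s[1] <- g$start
    e <- pmin(s + ex_w, g$end)
    s[n_ex] <- g$end - ex_w[n_ex]
    e[n_ex] <- g$end
    red <- IRanges::reduce(IRanges::IRanges(s + 1L, e))
    tibble(chrom = g$chrom, start = IRanges::start(red) - 1L, end = IRanges::end(red),
           gene_id = g$gene_id)
  })
  cgis <- map_dfr(chroms, function(ch) {
    x <- per_chrom[[ch]]$cgis
    tibble(chrom = ch, start = x$start, end = x$end, cgi_id = x$cgi_id)
  })
  te <- map_dfr(chroms, function(ch) {
    x <- per_chrom[[ch]]$te
    tibble(chrom = ch, start = x$start, end = x$end, subfamily = x$subfamily)
  }) |>
    left_join(cfg$te_catalog[, c("subfamily", "family", "class", "enhancer_like")],
              by = "subfamily")

  coding_tss <- genes |>
    mutate(pos = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
           class = "coding") |>
    select("chrom", "pos", "class")
  other_tss <- map_dfr(chroms, function(ch) {
    n <- cfg$n_mirna_tss + cfg$n_lnc_tss
    tibble(chrom = ch,
           pos = sort(sample.int(cfg$chrom_length - 1000L, n) + 500L),
           class = rep(c("miRNA", "lncRNA"), c(cfg$n_mirna_tss, cfg$n_lnc_tss)))
  })
  tss <- bind_rows(coding_tss, other_tss)
  promoters <- tss |>
    transmute(chrom = .data$chrom,
              start = pmax(.data$pos - 500L, 0L),
              end = pmin(.data$pos + 500L, cfg$chrom_length),
              tss_class = .data$class)

  cpg <- map_dfr(chroms, function(ch) {
    pos <- per_chrom[[ch]]$cpg_pos
    tibble(chrom = ch, pos = pos,
           is_mre = as.logical(rbinom(length(pos), 1, cfg$mre_fraction)))
  })

  windows <- make_windows(chrom_sizes, cfg$window_width)
  windows$cpg_count <- count_positions_per_window(cpg, windows)
  windows$mre_site_count <- count_positions_per_window(cpg[cpg$is_mre, ], windows)

  structure(list(chrom_sizes = chrom_sizes, windows = windows, cpg = cpg,
                 cgis = cgis, genes = genes, exons = exons,
                 promoters = promoters, tss = tss, te = te,
                 x_like_chrom = chroms[length(chroms)], config = cfg),
            class = "toy_genome")
}

#' Simulate multi-cell-line chromatin-state segmentations
#'
#' Paints each chromosome (at 100 bp resolution, then run-length encoded into
#' segments) with background states, promoter-type states around TSSs, and
#' enhancer-type states over enhancer-like TE copies plus random intergenic
#' sites. Per cell line the segments are non-overlapping and tile each
#' chromosome exactly.
#'
#' @param genome A [generate_genome()] result.
#' @param n_cell_lines Number of cell lines (>= 2).
#' @param seed Integer seed.
#' @param p_tss_promoter Probability that a given TSS is painted with a
#'   promoter state in a given cell line.
#' @param p_te_enhancer Probability that an enhancer-like TE copy is painted
#'   with an enhancer state in a given cell line.
#' @param n_random_enhancers Random intergenic enhancer sites per chromosome
#'   per cell line.
#' @return A tibble with `chrom`, `start`, `end`, `state`, `cell_line`.
#' @export
simulate_chromhmm <- function(genome, n_cell_lines = 2L, seed = 1L,
                              p_tss_promoter = 0.8, p_te_enhancer = 0.6,
                              n_random_enhancers = 30L) {
  stopifnot(n_cell_lines >= 2)
  set.seed(seed)
  res <- 100L
  bg_states <- c("Txn", "Het", "Quies", "Ins")
  map_dfr(seq_len(n_cell_lines), function(cl) {
    cl_name <- paste0("cell", cl)
    map_dfr(seq_len(nrow(genome$chrom_sizes)), function(ci) {
      ch <- genome$chrom_sizes$chrom[ci]
      len <- genome$chrom_sizes$size[ci]
      n_cells <- ceiling(len / res)
      # background: segments with geometric lengths
      lab <- integer(n_cells)
      i <- 1L
      while (i <= n_cells) {
        seg_len <- 1L + stats::rgeom(1, res / 2000)
        lab[i:min(i + seg_len - 1L, n_cells)] <- sample.int(length(bg_states), 1L)
        i <- i + seg_len
      }
      paint <- bg_states[lab]
      paint_interval <- function(paint, s, e, state) {
        cs <- max(floor(s / res) + 1L, 1L)
        ce <- min(ceiling(e / res), n_cells)
        if (cs <= ce) paint[cs:ce] <- state
        paint
      }
      tss <- genome$tss[genome$tss$chrom == ch, ]
      for (j in seq_len(nrow(tss))) {
        if (runif(1) < p_tss_promoter) {
          paint <- paint_interval(paint, tss$pos[j] - 500L, tss$pos[j] + 500L, "Tss")
        }
      }
      te <- genome$te[genome$te$chrom == ch & genome$te$enhancer_like, ]
      for (j in seq_len(nrow(te))) {
        if (runif(1) < p_te_enhancer) {
          paint <- paint_interval(paint, te$start[j], te$end[j], "Enh")
        }
      }
      for (j in seq_len(n_random_enhancers)) {
        s <- sample.int(len - 600L, 1L)
        paint <- paint_interval(paint, s, s + sample(200:600, 1L), "Enh")
      }
      r <- rle(paint)
      ends <- cumsum(r$lengths) * res
      ends[length(ends)] <- len
      starts <- c(0, head(ends, -1))
      tibble(chrom = ch, start = as.integer(starts), end = as.integer(ends),
             state = r$values, cell_line = cl_name)
    })
  })
}

#' Default mapping from chromatin-state labels to regulatory classes
#'
#' @return Named character vector: state label -> one of `promoter`,
#'   `enhancer`, `other`.
#' @export
default_state_map <- function() {
  c(Tss = "promoter", TssF = "promoter",
    Enh = "enhancer", EnhF = "enhancer",
    Txn = "other", Het = "other", Quies = "other", Ins = "other")
}
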