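# Genomic and regulatory context of consensus DMRs: feature catalog,
# exclusive context labels, window-based feature enrichment, CGI/shore
# patterns.

gr_setdiff_tbl <- function(x, y) {
  # interval set difference on tibbles (chrom/start/end), 0-based half-open
  if (nrow(x) == 0) return(x[c("chrom", "start", "end")])
  if (nrow(y) == 0) return(x[c("chrom", "start", "end")])
  d <- GenomicRanges::setdiff(as_granges0(x), GenomicRanges::reduce(as_granges0(y)))
  tibble(chrom = as.character(GenomicRanges::seqnames(d)),
         start = GenomicRanges::start(d) - 1L,
         end = GenomicRanges::end(d))
}

#' Build the feature catalog of a toy genome
#'
#' Derives CpG-island shores (the flanking 1 kb on each side of a CpG island,
#' with island bodies subtracted so shores never overlap any island), introns
#' (gene bodies minus exons), and intergenic space (genome minus gene bodies
#' and promoters) from the genome's primary annotations.
#'
#' @param genome A [generate_genome()] result.
#' @return A list of class `feature_catalog` with interval tibbles `cgis`,
#'   `shores` (with `cgi_id` and `side`), `promoters`, `exons`, `introns`,
#'   `gene_bodies`, `intergenic`, `te`, and the window frame `windows`.
#' @export
feature_catalog <- function(genome) {
  cgis <- genome$cgis
  sizes <- setNames(genome$chrom_sizes$size, genome$chrom_sizes$chrom)
  flank <- bind_rows(
    tibble(chrom = cgis$chrom, start = pmax(cgis$start - 1000L, 0L),
           end = cgis$start, cgi_id = cgis$cgi_id, side = "left"),
    tibble(chrom = cgis$chrom, start = cgis$end,
           end = pmin(cgis$end + 1000L, sizes[cgis$chrom]), cgi_id = cgis$cgi_id,
           side = "right")
  ) |> filter(.data$end > .data$start)
  # subtract any CGI body overlapping a flank, preserving the flank's identity
  hits <- overlap_join(flank, cgis)
  shores <- flank
  if (nrow(hits) > 0) {
    trimmed <- map_dfr(unique(hits$query), function(q) {
      pieces <- gr_setdiff_tbl(flank[q, ], cgis[hits$subject[hits$query == q], ])
      if (nrow(pieces) == 0) return(NULL)
      mutate(pieces, cgi_id = flank$cgi_id[q], side = flank$side[q])
    })
    shores <- bind_rows(flank[-unique(hits$query), ], trimmed) |>
      arrange(.data$chrom, .data$start)
  }
  gene_bodies <- genome$genes[c("chrom", "start", "end", "gene_id")]
  introns <- gr_setdiff_tbl(gene_bodies, genome$exons)
  genome_tbl <- tibble(chrom = genome$chrom_sizes$chrom, start = 0L,
                       end = genome$chrom_sizes$size)
  intergenic <- gr_setdiff_tbl(genome_tbl,
                               bind_rows(gene_bodies[c("chrom", "start", "end")],
                                         genome$promoters[c("chrom", "start", "end")]))
  structure(list(cgis = cgis, shores = shores,
                 promoters = genome$promoters, exons = genome$exons,
                 introns = introns, gene_bodies = gene_bodies,
                 intergenic = intergenic, te = genome$te,
                 windows = genome$windows),
            class = "feature_catalog")
}

#' Exclusive genomic context of each DMR
#'
#' Assigns one exclusive context label per DMR with the priority
#' promoter > exon > intron > intergenic, and reports CpG-island, shore and
#' transposable-element membership as independent boolean flags.
#'
#' @param dmrs Tibble with `chrom`, `start`, `end`.
#' @param catalog A [feature_catalog()].
#' @return `dmrs` with columns `context`, `in_cgi`, `in_shore`, `in_te` added.
#' @export
classify_context <- function(dmrs, catalog) {
  if (nrow(dmrs) == 0) {
    return(mutate(dmrs, context = character(0), in_cgi = logical(0),
                  in_shore = logical(0), in_te = logical(0)))
  }
  in_prom <- overlap_count(dmrs, catalog$promoters) > 0
  in_exon <- overlap_count(dmrs, catalog$exons) > 0
  in_intron <- overlap_count(dmrs, catalog$introns) > 0
  dmrs |>
    mutate(context = case_when(in_prom ~ "promoter",
                               in_exon ~ "exon",
                               in_intron ~ "intron",
                               TRUE ~ "intergenic"),
           in_cgi = overlap_count(dmrs, catalog$cgis) > 0,
           in_shore = overlap_count(dmrs, catalog$shores) > 0,
           in_te = overlap_count(dmrs, catalog$te) > 0)
}

#' Window-based feature enrichment of a DMR set
#'
#' For each feature set, the enrichment score is
#' `ES = (n_hit / n_DMR) / (N_hit / N_all)`, where `n_hit` counts DMRs
#' containing the feature, `n_DMR` is the DMR total, `N_hit` counts genomic
#' windows carrying the feature and `N_all` is the total window count. A
#' one-sided binomial test (success probability `N_hit / N_all` over `n_DMR`
#' trials) supplies a p-value, BH-adjusted across the feature batch; features
#' with `ES > 5` and `q < 0.05` are flagged. Features absent from the window
#' frame (`N_hit = 0`) are reported with missing `ES`.
#'
#' @param dmrs Tibble of DMR intervals (`chrom`, `start`, `end`).
#' @param features Named list of feature interval tibbles.
#' @param windows Window frame defining the genomic background.
#' @return A tibble with one row per feature: `feature`, `n_hit`, `n_dmr`,
#'   `N_hit`, `N_all`, `es`, `p_value`, `q_value`, `flag_5fold`.
#' @export
feature_enrichment <- function(dmrs, features, windows) {
  stopifnot(nrow(dmrs) > 0, length(features) > 0, !is.null(names(features)))
  n_dmr <- nrow(dmrs)
  n_all <- nrow(windows)
  out <- map_dfr(names(features), function(nm) {
    feat <- features[[nm]]
    n_hit <- sum(overlap_count(dmrs, feat) > 0)
    N_hit <- sum(overlap_count(windows, feat) > 0)
    tibble(feature = nm, n_hit = n_hit, n_dmr = n_dmr,
           N_hit = N_hit, N_all = n_all)
  })
  out |>
    mutate(es = ifelse(.data$N_hit > 0,
                       (.data$n_hit / .data$n_dmr) / (.data$N_hit / .data$N_all),
                       NA_real_),
           p_value = ifelse(.data$N_hit > 0,
                            pbinom(.data$n_hit - 1L, .data$n_dmr,
                                   .data$N_hit / .data$N_all, lower.tail = FALSE),
                            NA_real_),
           q_value = {
             q <- rep(NA_real_, n())
             ok <- !is.na(.data$p_value)
             q[ok] <- bh_adjust(.data$p_value[ok])
             q
           },
           flag_5fold = !is.na(.data$es) & .data$es > 5 & !is.na(.data$q_value) &
             .data$q_value < 0.05)
}

#' CpG-island / shore methylation-change patterns
#'
#' Classifies each CpG island, separately per change direction, into one of
#' `CGI-only` (a DMR window of that direction overlaps the island body but no
#' flank), `CGI+shore` (body and at least one flank), `shore-only` (a flank
#' but not the body) or `none`.
#'
#' @param catalog A [feature_catalog()] (supplies islands and their paired
#'   shores).
#' @param dmrs Tibble of DMRs with `chrom`, `start`, `end`, `direction`.
#' @return A tibble with one row per island x direction:
#'   `cgi_id`, `direction`, `category`.
#' @export
cgi_shore_patterns <- function(catalog, dmrs) {
  cgis <- catalog$cgis
  shores <- catalog$shores
  map_dfr(c("hyper", "hypo"), function(dir) {
    d <- dmrs[dmrs$direction == dir, ]
    body_hit <- if (nrow(d) > 0) overlap_count(cgis, d) > 0 else rep(FALSE, nrow(cgis))
    shore_hit_ids <- if (nrow(d) > 0) {
      unique(shores$cgi_id[overlap_count(shores, d) > 0])
    } else character(0)
    shore_hit <- cgis$cgi_id %in% shore_hit_ids
    tibble(cgi_id = cgis$cgi_id, direction = dir,
           category = case_when(body_hit & shore_hit ~ "CGI+shore",
                                body_hit ~ "CGI-only",
                                shore_hit ~ "shore-only",
                                TRUE ~ "none"))
  })
}
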