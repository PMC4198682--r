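#' @keywords internal
"_PACKAGE"

#' @import dplyr
#' @import tibble
#' @importFrom rlang .data abort
#' @importFrom purrr map map_dfr map2 imap pmap
#' @importFrom stats pbinom dbinom qnorm pnorm p.adjust rpois rbinom rnorm rbeta runif setNames
#' @importFrom utils head tail
NULL

# All genomic coordinates in this package are 0-based half-open [start, end),
# the BED convention, including windows. GRanges conversion (1-based closed)
# happens only inside overlap helpers.

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s at row %d: start=%s end=%s (need 0 <= start < end)",
                  what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

#' Read a BED file into a tibble of genomic intervals
#'
#' Reads BED3/BED6(+) with 0-based half-open coordinates. Track definition
#' lines, comment lines (`#`) and blank lines are skipped. Input order is
#' preserved. Lines with non-integer coordinates or `start >= end` raise an
#' error naming the offending line.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand` (additional columns are kept as
#'   `extra1`, `extra2`, ...).
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- length(fields[[1]])
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3) {
      abort(sprintf("malformed BED line %d: fewer than 3 columns", idx[i]))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("malformed BED line %d: non-integer coordinates", idx[i]))
    }
    if (start < 0 || start >= end) {
      abort(sprintf("malformed BED line %d: start %d >= end %d violates 0-based half-open convention",
                    idx[i], start, end))
    }
    f
  })
  ncols <- max(lengths(rows))
  mat <- t(vapply(rows, function(f) c(f, rep(NA_character_, ncols - length(f))), character(ncols)))
  std <- c("chrom", "start", "end", "name", "score", "strand")
  nm <- c(std[seq_len(min(ncols, 6))],
          if (ncols > 6) paste0("extra", seq_len(ncols - 6)))
  out <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE), .name_repair = "minimal")
  names(out) <- nm
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if ("score" %in% names(out)) out$score <- suppressWarnings(as.numeric(out$score))
  out
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab-separated file with chromosome name and length.
#' @return A tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "integer"))
  as_tibble(x)
}

#' Read a RepeatMasker-style transposable-element table
#'
#' Expects a tab-separated table with a header row in the UCSC rmsk dialect.
#' The column mapping is configurable for other dialects. The
#' subfamily -> (family, class) map is built and checked for consistency: a
#' subfamily appearing with two different family/class assignments is an error.
#'
#' @param path Path to the table.
#' @param col_map Named character vector mapping the fields
#'   `chrom`, `start`, `end`, `subfamily`, `class`, `family` to column names
#'   in the file. Defaults to the UCSC rmsk column names.
#' @return A tibble with columns `chrom`, `start`, `end`, `subfamily`,
#'   `family`, `class`.
#' @export
read_repeatmasker_table <- function(path,
                                    col_map = c(chrom = "genoName", start = "genoStart",
                                                end = "genoEnd", subfamily = "repName",
                                                class = "repClass", family = "repFamily")) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "")
  missing_cols <- setdiff(unname(col_map), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns in RepeatMasker table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    chrom = as.character(x[[col_map[["chrom"]]]]),
    start = as.integer(x[[col_map[["start"]]]]),
    end = as.integer(x[[col_map[["end"]]]]),
    subfamily = as.character(x[[col_map[["subfamily"]]]]),
    family = as.character(x[[col_map[["family"]]]]),
    class = as.character(x[[col_map[["class"]]]])
  )
  if (nrow(out) > 0) {
    validate_intervals(out, "TE annotation")
    maps <- distinct(out, .data$subfamily, .data$family, .data$class)
    dup <- maps$subfamily[duplicated(maps$subfamily)]
    if (length(dup) > 0) {
      abort(paste0("inconsistent subfamily -> family/class mapping for: ",
                   paste(unique(dup), collapse = ", ")))
    }
  }
  out
}

#' Tile chromosomes with fixed-width windows
#'
#' Windows tile each chromosome without overlap from position 0; the last
#' window of a chromosome is truncated at the chromosome end. Chromosomes are
#' emitted in input order.
#'
#' @param chrom_sizes A tibble with columns `chrom` and `size`, or a named
#'   numeric vector of chromosome lengths.
#' @param width Window width in bases (default 500).
#' @return A tibble with columns `chrom`, `start`, `end`, `win_id` (1-based
#'   integer index over the whole frame).
#' @export
make_windows <- function(chrom_sizes, width = 500L) {
  stopifnot(width > 0)
  if (!is.data.frame(chrom_sizes)) {
    chrom_sizes <- tibble(chrom = names(chrom_sizes), size = as.integer(chrom_sizes))
  }
  stopifnot(all(chrom_sizes$size > 0))
  out <- map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
    len <- chrom_sizes$size[i]
    starts <- seq.int(0L, len - 1L, by = width)
    tibble(chrom = chrom_sizes$chrom[i],
           start = as.integer(starts),
           end = as.integer(pmin(starts + width, len)))
  })
  out$win_id <- seq_len(nrow(out))
  out
}

as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Overlap join between two interval tables
#'
#' Computes all pairs of overlapping intervals between `queries` and
#' `subjects` under half-open intersection: zero-length intersections (bookend
#' intervals) are not overlaps. Strand is ignored.
#'
#' @param queries,subjects Tibbles with columns `chrom`, `start`, `end`.
#' @return A tibble with columns `query` (row index into `queries`), `subject`
#'   (row index into `subjects`) and `overlap` (intersection length in bases),
#'   ordered by `query`.
#' @export
overlap_join <- function(queries, subjects) {
  validate_intervals(queries, "query")
  validate_intervals(subjects, "subject")
  if (nrow(queries) == 0 || nrow(subjects) == 0) {
    return(tibble(query = integer(), subject = integer(), overlap = integer()))
  }
  qg <- as_granges0(queries)
  sg <- as_granges0(subjects)
  hits <- GenomicRanges::findOverlaps(qg, sg, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(queries$end[qi], subjects$end[si]) - pmax(queries$start[qi], subjects$start[si])
  tibble(query = qi, subject = si, overlap = as.integer(ov)) |>
    arrange(.data$query, .data$subject)
}

#' Count overlapping subjects per query interval
#'
#' @inheritParams overlap_join
#' @return Integer vector of length `nrow(queries)`: number of subjects each
#'   query overlaps by at least 1 bp.
#' @export
overlap_count <- function(queries, subjects) {
  hits <- overlap_join(queries, subjects)
  out <- integer(nrow(queries))
  if (nrow(hits) > 0) {
    tab <- table(hits$query)
    out[as.integer(names(tab))] <- as.integer(tab)
  }
  out
}

#' Write a consensus DMR table as BED6+
#'
#' Writes one data line per DMR: chrom, start, end, direction (BED name
#' column), q-value (BED score column), support count, then any further
#' annotation columns. A `#`-prefixed header line records column names, so the
#' file round-trips through [read_bed()].
#'
#' @param dmrs A tibble with at least `chrom`, `start`, `end`, `direction`;
#'   optional `q_value`, `support` and further columns are appended.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(dmrs, path) {
  stopifnot(is.data.frame(dmrs))
  cols <- c("chrom", "start", "end", "direction")
  stopifnot(all(cols %in% names(dmrs)) || nrow(dmrs) == 0)
  q <- if ("q_value" %in% names(dmrs)) dmrs$q_value else rep(NA_real_, nrow(dmrs))
  supp <- if ("support" %in% names(dmrs)) dmrs$support else rep(NA_integer_, nrow(dmrs))
  extra <- dmrs[setdiff(names(dmrs), c(cols, "q_value", "support", "win_id"))]
  out <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    direction = dmrs$direction, q_value = q, support = supp,
                    check.names = FALSE)
  if (ncol(extra) > 0) out <- cbind(out, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(out), collapse = "\t")), con)
  if (nrow(out) > 0) {
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Assign intervals to the windows they intersect
#'
#' A region "is in" a window iff it overlaps at least 1 bp of it; a region
#' spanning several windows maps to all of them.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param windows A window frame from [make_windows()].
#' @return A tibble with columns `row` (interval row index) and `win_id`.
#' @export
intervals_to_windows <- function(intervals, windows) {
  hits <- overlap_join(intervals, windows)
  tibble(row = hits$query, win_id = windows$win_id[hits$subject])
}

# positions (0-based) -> per-window counts over a window frame
count_positions_per_window <- function(positions, windows) {
  # positions: tibble(chrom, pos)
  out <- integer(nrow(windows))
  if (nrow(positions) == 0) return(out)
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    pos <- positions$pos[positions$chrom == ch]
    if (length(pos) == 0) next
    # windows are contiguous fixed-width tiles per chromosome
    idx <- findInterval(pos, windows$start[wi])
    idx <- idx[idx >= 1 & pos < windows$end[wi[pmax(idx, 1)]]]
    tab <- tabulate(idx, nbins = length(wi))
    out[wi] <- out[wi] + tab
  }
  out
}
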