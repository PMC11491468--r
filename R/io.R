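#' Read a segment table
#'
#' Reads SEG-style segment files into a [segment_profile()]. Two dialects
#' are supported: `"seg"`, the classic DNAcopy/cBioPortal layout
#' (`ID, chrom, loc.start, loc.end, num.mark, seg.mean`), and `"tsv"`, a
#' plain layout (`sample, chrom, start, end, value` plus optional
#' `n_bins, called, abs_cn, altered`). Coordinates are 1-based inclusive in
#' the file and kept that way internally. Values may be stored as log2
#' ratios (common for SNP-array segment output) or linear ratios; the
#' package works on the linear scale, so log2 input is converted with
#' `2^value` at the boundary. Unknown extra columns are preserved and
#' written back by [write_segments()].
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect `"seg"` or `"tsv"`.
#' @param value_scale scale of the value column: `"linear"` (default) or
#'   `"log2"`.
#' @param include_sex keep X/Y segments? Default drops them with a warning.
#' @return a [segment_profile()].
#' @export
read_segments <- function(path, dialect = c("seg", "tsv"),
                          value_scale = c("linear", "log2"),
                          include_sex = FALSE) {
  dialect <- match.arg(dialect)
  value_scale <- match.arg(value_scale)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  cols <- if (dialect == "seg") {
    c(sample = "ID", chrom = "chrom", start = "loc.start",
      end = "loc.end", n_bins = "num.mark", value = "seg.mean")
  } else {
    c(sample = "sample", chrom = "chrom", start = "start",
      end = "end", value = "value")
  }
  missing_cols <- setdiff(unname(cols[c("sample", "chrom", "start", "end", "value")]),
                          names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  segs <- data.frame(chrom = as.character(raw[[cols["chrom"]]]),
                     start = raw[[cols["start"]]],
                     end = raw[[cols["end"]]],
                     value = raw[[cols["value"]]],
                     stringsAsFactors = FALSE)
  bad <- which(!is.finite(segs$start) | !is.finite(segs$end) |
                 !is.finite(segs$value))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  known <- unname(cols)
  for (extra in setdiff(names(raw), known)) segs[[extra]] <- raw[[extra]]
  if (!is.na(cols["n_bins"]) && cols["n_bins"] %in% names(raw))
    segs$n_bins <- raw[[cols["n_bins"]]]
  if (dialect == "tsv")
    for (opt in c("n_bins", "called", "abs_cn", "altered"))
      if (opt %in% names(raw)) segs[[opt]] <- raw[[opt]]
  if (value_scale == "log2") segs$value <- 2^segs$value
  if (!include_sex && any(sex <- is_sex_chrom(segs$chrom))) {
    warning(sum(sex), " sex-chromosome segment(s) dropped")
    segs <- segs[!sex, , drop = FALSE]
  }
  sample_ids <- unique(as.character(raw[[cols["sample"]]]))
  if (length(sample_ids) > 1)
    stop("file contains multiple samples: ", paste(sample_ids, collapse = ", "))
  segment_profile(sample_ids[1] %||% "sample", segs)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Write a segment table
#'
#' Inverse of [read_segments()]; always writes linear values. Extra columns
#' carried on the profile are appended after the dialect's standard
#' columns, so `read_segments(write_segments(x))` round-trips.
#'
#' @param profile a [segment_profile()].
#' @param path output path.
#' @param dialect `"seg"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profile, path, dialect = c("seg", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(profile, "segment_profile"))
  s <- profile$segments
  out <- if (dialect == "seg") {
    data.frame(ID = profile$sample_id, chrom = s$chrom,
               `loc.start` = s$start, `loc.end` = s$end,
               `num.mark` = s$n_bins, `seg.mean` = s$value,
               check.names = FALSE)
  } else {
    data.frame(sample = profile$sample_id, chrom = s$chrom,
               start = s$start, end = s$end, value = s$value,
               n_bins = s$n_bins, called = s$called,
               abs_cn = s$abs_cn, altered = s$altered)
  }
  std <- c("chrom", "start", "end", "value", "n_bins", "called",
           "abs_cn", "altered")
  for (extra in setdiff(names(s), std)) out[[extra]] <- s[[extra]]
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a bin-level ratio table
#'
#' Reads a tab-separated `chrom, start, end, ratio` table and validates the
#' bins against a genome layout grid: every bin must start on a layout grid
#' position and not exceed the layout bin size. Bins on chromosomes absent
#' from the layout are rejected, except sex chromosomes when the layout
#' excludes them, which are dropped with a warning.
#'
#' @param path path to the table.
#' @param layout a [genome_layout()].
#' @param sample_id sample name for the resulting profile; defaults to the
#'   file name.
#' @return a [bin_profile()].
#' @export
read_bins <- function(path, layout, sample_id = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "ratio")
  if (!all(need %in% names(raw)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  if (nrow(raw) == 0) stop("no bins in ", path)
  raw$chrom <- as.character(raw$chrom)
  off_layout <- !(raw$chrom %in% layout$chromosomes$name)
  if (any(off_layout)) {
    sex <- is_sex_chrom(raw$chrom)
    if (!layout$include_sex && any(off_layout & sex)) {
      warning(sum(off_layout & sex),
              " sex-chromosome bin(s) dropped (layout excludes sex chromosomes)")
      raw <- raw[!(off_layout & sex), , drop = FALSE]
      off_layout <- !(raw$chrom %in% layout$chromosomes$name)
    }
    if (any(off_layout))
      stop("bins on chromosome(s) not in layout: ",
           paste(unique(raw$chrom[off_layout]), collapse = ", "))
  }
  if (nrow(raw) == 0) stop("no bins in ", path)
  if (any((raw$start - 1) %% layout$bin_size != 0))
    stop("bin start not aligned to the layout grid")
  bin_profile(sample_id %||% basename(path), layout, raw)
}

#' Write a bin-level ratio table
#' @param bins a [bin_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  stopifnot(inherits(bins, "bin_profile"))
  utils::write.table(bins$bins[, c("chrom", "start", "end", "ratio")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
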