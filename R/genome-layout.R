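#' Genome layout for binned copy-number analysis
#'
#' A layout is the fixed coordinate frame every bin- and segment-level track
#' in the package is defined on: an ordered set of chromosomes with lengths,
#' and a bin size used to tile them. Coordinates are 1-based inclusive
#' throughout (SEG convention).
#'
#' @param chromosomes data.frame with columns `name` (character) and
#'   `length` (bp, positive integer-ish).
#' @param bin_size bin width in bp (default 500 kbp, the resolution used for
#'   low-coverage WGS read-depth profiling).
#' @param include_sex keep chromosomes named X/Y (with or without "chr"
#'   prefix)? Default `FALSE`: sex chromosomes are excluded from copy-number
#'   analysis.
#' @return object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, bin_size = 5e5, include_sex = FALSE) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome names in layout")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be > 0")
  if (!isTRUE(include_sex)) {
    sex <- is_sex_chrom(chromosomes$name)
    chromosomes <- chromosomes[!sex, , drop = FALSE]
  }
  if (nrow(chromosomes) == 0L) stop("layout has no chromosomes")
  if (!(is.numeric(bin_size) && length(bin_size) == 1L && bin_size > 0))
    stop("bin_size must be a single positive number")
  structure(
    list(chromosomes = chromosomes[, c("name", "length")],
         bin_size = as.numeric(bin_size),
         include_sex = isTRUE(include_sex)),
    class = "genome_layout"
  )
}

is_sex_chrom <- function(x) {
  toupper(sub("^chr", "", x)) %in% c("X", "Y")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosomes, %.3g Gb, bin %g kb%s\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e9,
              x$bin_size / 1e3,
              if (x$include_sex) ", sex chromosomes kept" else ""))
  invisible(x)
}

# hg19 (GRCh37) autosome lengths, bp
.HG19_AUTOSOMES <- data.frame(
  name = as.character(1:22),
  length = c(249250621, 243199373, 198022430, 191154276, 180915260,
             171115067, 159138663, 146364022, 141213431, 135534747,
             135006516, 133851895, 115169878, 107349540, 102531392,
             90354753, 81195210, 78077248, 59128983, 63025520,
             48129895, 51304566)
)

#' Default hg19 autosome layout
#'
#' @inheritParams genome_layout
#' @return `genome_layout` over the 22 autosomes of GRCh37.
#' @export
hg19_layout <- function(bin_size = 5e5, include_sex = FALSE) {
  genome_layout(.HG19_AUTOSOMES, bin_size = bin_size, include_sex = include_sex)
}

#' Small toy layout for examples and tests
#'
#' Three 50-Mb chromosomes; 300 bins at the default 500-kb bin size. Big
#' enough to host multi-segment profiles, small enough for fast simulation.
#'
#' @inheritParams genome_layout
#' @return `genome_layout`.
#' @export
toy_layout <- function(bin_size = 5e5) {
  genome_layout(data.frame(name = c("1", "2", "3"), length = rep(5e7, 3)),
                bin_size = bin_size)
}

#' Tile a layout into bins
#'
#' @param layout a `genome_layout`.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive); the last
#'   bin of a chromosome is truncated at the chromosome end, so
#'   `end - start + 1 <= bin_size`.
#' @export
layout_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  pieces <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    len <- layout$chromosomes$length[i]
    starts <- seq(1, len, by = layout$bin_size)
    data.frame(chrom = layout$chromosomes$name[i],
               start = starts,
               end = pmin(starts + layout$bin_size - 1, len))
  })
  do.call(rbind, pieces)
}

#' Number of bins a layout tiles into
#' @param layout a `genome_layout`.
#' @return integer count, `sum(ceiling(length / bin_size))`.
#' @export
n_layout_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(ceiling(layout$chromosomes$length / layout$bin_size))
}
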