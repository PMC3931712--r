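# Coordinate conventions: all internal coordinates are 0-based, half-open
# [start, end). GFF input (1-based inclusive) is converted on read.

#' The 21 histone methylation marks and their activity classes
#'
#' Canonical ordering of the histone modifications considered by the method,
#' with each mark's association class: "active" marks associate with
#' expressed genes and enhancers, "repressive" with silenced chromatin, and
#' "moderate" marks show no clear preference.
#'
#' @return A data.frame with columns `mark` and `class`, one row per
#'   modification, in canonical order.
#' @export
#' @examples
#' histone_marks()
histone_marks <- function() {
  data.frame(
    mark = c("H2A.Z", "H3K4me1", "H3K4me2", "H3K4me3", "H3K9me1",
             "H3K9me2", "H3K9me3", "H3K27me1", "H3K27me2", "H3K27me3",
             "H3K36me1", "H3K36me3", "H3K79me1", "H3K79me2", "H3K79me3",
             "H3R2me1", "H3R2me2", "H4K20me1", "H4K20me3", "H4R3me2",
             "H2BK5me1"),
    class = c("active", "active", "active", "active", "active",
              "repressive", "repressive", "active", "moderate", "repressive",
              "moderate", "active", "moderate", "moderate", "moderate",
              "moderate", "moderate", "active", "moderate", "moderate",
              "active"),
    stringsAsFactors = FALSE
  )
}

#' The eight marks most predictive of binding regions
#'
#' The subset of [histone_marks()] found to correlate strongly with
#' transcription-factor binding regions (all of class "active").
#'
#' @return Character vector of eight mark names.
#' @export
top_marks <- function() {
  c("H2A.Z", "H3K4me1", "H3K4me2", "H3K4me3", "H3K9me1", "H3K27me1",
    "H4K20me1", "H2BK5me1")
}

#' Partition a chromosome into fixed-width bins
#'
#' Produces consecutive, non-overlapping bins of width `bin_size` covering a
#' prefix of `[0, chrom_length)`. A trailing partial bin shorter than
#' `bin_size` is dropped so that every bin has uniform width (keeping
#' occupancy counts comparable across bins).
#'
#' @param chrom_length Chromosome length in bp (> 0).
#' @param bin_size Bin width in bp (> 0, default 1000).
#' @return data.frame with 0-based half-open `start` and `end` columns.
#' @export
#' @examples
#' bin_chromosome(2500)          # two bins; the trailing 500 bp are dropped
bin_chromosome <- function(chrom_length, bin_size = 1000L) {
  if (length(chrom_length) != 1L || !is.finite(chrom_length) || chrom_length <= 0)
    stop("'chrom_length' must be a single positive number")
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0)
    stop("'bin_size' must be a single positive number")
  n <- floor(chrom_length / bin_size)
  if (n == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  start <- as.integer((seq_len(n) - 1L) * bin_size)
  data.frame(start = start, end = start + as.integer(bin_size))
}

#' Center of a genomic interval
#'
#' Returns `start + floor((end - start)/2)`; for even lengths this picks the
#' right of the two middle bases (a fixed deterministic convention).
#'
#' @param start,end 0-based half-open coordinates (vectorized); `start < end`.
#' @return Integer center position(s).
#' @export
#' @examples
#' interval_center(0, 1000)  # 500
#' interval_center(0, 7)     # 3
interval_center <- function(start, end) {
  if (any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  as.integer(start + (end - start) %/% 2)
}

#' Construct a set of binding sites for one transcription factor
#'
#' @param chrom Chromosome name per site.
#' @param start,end 0-based half-open site coordinates.
#' @param strand "+" or "-" per site.
#' @param tf_name Transcription factor name.
#' @return An object of class `binding_sites`: a data.frame with columns
#'   `chrom`, `start`, `end`, `strand`, `center`, sorted by (chrom, start),
#'   with the TF name stored as attribute `tf_name`.
#' @export
binding_sites <- function(chrom, start, end, strand = "+", tf_name = "TF") {
  if (length(chrom) == 0L) stop("empty binding-site set")
  strand <- rep_len(strand, length(chrom))
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, stringsAsFactors = FALSE)
  df$center <- interval_center(df$start, df$end)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "tf_name") <- tf_name
  class(df) <- c("binding_sites", "data.frame")
  df
}

#' Construct a nucleosome-center track for one histone mark
#'
#' Centers are deduplicated and sorted per chromosome: the track represents a
#' set of nucleosome positions, not a coverage signal.
#'
#' @param mark Histone modification name (e.g. "H3K4me3").
#' @param chrom Chromosome name per center.
#' @param center 0-based nucleosome center coordinate per entry.
#' @return An object of class `nuc_track`: a list with elements `mark` and
#'   `centers` (a named list of strictly increasing integer vectors, one per
#'   chromosome).
#' @export
nucleosome_track <- function(mark, chrom, center) {
  if (length(chrom) != length(center))
    stop("'chrom' and 'center' lengths differ")
  if (length(center) && (any(!is.finite(center)) || any(center != floor(center))))
    stop("nucleosome centers must be integer coordinates")
  centers <- lapply(split(as.integer(center), as.character(chrom)),
                    function(x) sort(unique(x)))
  structure(list(mark = mark, centers = centers), class = "nuc_track")
}

#' @export
print.nuc_track <- function(x, ...) {
  n <- sum(lengths(x$centers))
  cat(sprintf("<nuc_track> mark %s: %d centers on %d chromosome(s)\n",
              x$mark, n, length(x$centers)))
  invisible(x)
}

#' @export
print.binding_sites <- function(x, ...) {
  cat(sprintf("<binding_sites> %s: %d sites on %d chromosome(s)\n",
              attr(x, "tf_name"), nrow(x), length(unique(x$chrom))))
  NextMethod()
}

#' Maximal assembly-gap-free regions of a sequence
#'
#' Finds maximal runs of A/C/G/T (no N or other ambiguity codes) of at least
#' `min_len` bp. These are the regions eligible for negative-control
#' sampling, where a full flanking window of real sequence exists.
#'
#' @param seq Chromosome sequence (single character string).
#' @param min_len Minimum run length to report (default 1000 bp).
#' @return data.frame of 0-based half-open `start`, `end`.
#' @export
nongap_regions <- function(seq, min_len = 1000L) {
  codes <- .dna_codes(seq)
  good <- !is.na(codes)
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

# map characters to 1..4 (A,C,G,T; case-insensitive); anything else -> NA
.DNA_CODE <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("a")] <- 1L
  x[utf8ToInt("C")] <- 2L; x[utf8ToInt("c")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("g")] <- 3L
  x[utf8ToInt("T")] <- 4L; x[utf8ToInt("t")] <- 4L
  x
})

.DNA_BASES <- c("A", "C", "G", "T")

.dna_codes <- function(seq) {
  .DNA_CODE[utf8ToInt(seq)]
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (IUPAC codes accepted).
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
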