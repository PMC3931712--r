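# Readers and writers. Conventions: BED and internal coordinates are
# 0-based half-open; GFF is 1-based inclusive and converted on read/write.
# Output floats are fixed at 6 decimals so repeated runs diff cleanly.

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of chromosome sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param genome Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read binding sites from a GFF file
#'
#' Accepts GFF2 or GFF3. Records are selected for the requested factor by
#' matching `tf_name` against the feature type column and the common
#' attribute keys (`Name`, `name`, `ID`, `gene_id`). Coordinates are
#' converted from 1-based inclusive to 0-based half-open.
#'
#' @param path GFF path.
#' @param tf_name Factor name to select.
#' @return A [binding_sites()] object.
#' @export
read_gff_sites <- function(path, tf_name) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff"),
                 error = function(e)
                   stop("malformed GFF '", path, "': ",
                        conditionMessage(e)))
  if (length(gr) == 0L) stop("no records in ", path)
  md <- as.data.frame(gr)
  keep <- rep(FALSE, nrow(md))
  for (col in intersect(c("type", "Name", "name", "ID", "gene_id", "group"),
                        names(md)))
    keep <- keep | (!is.na(md[[col]]) & as.character(md[[col]]) == tf_name)
  if (!any(keep))
    stop("no records matching factor '", tf_name, "' in ", path)
  md <- md[keep, , drop = FALSE]
  strand <- as.character(md$strand)
  strand[!strand %in% c("+", "-")] <- "+"
  binding_sites(as.character(md$seqnames), md$start - 1L, md$end,
                strand, tf_name = tf_name)
}

#' Write binding sites as GFF3
#' @param sites A [binding_sites()] object.
#' @param path Output path.
#' @param source Value of the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff_sites <- function(sites, path, source = "epimotif") {
  tf <- attr(sites, "tf_name")
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tTFBS\t%d\t%d\t.\t%s\t.\tName=%s",
                     sites$chrom, source, sites$start + 1L, sites$end,
                     sites$strand, tf))
  writeLines(lines, path)
  invisible(path)
}

#' Read a nucleosome-center track
#'
#' Accepts a 2-column TSV (chrom, center) or BED3 (chrom, start, end); for
#' BED3 the center is the interval midpoint `floor((start + end) / 2)` in
#' 0-based coordinates. Rows are deduplicated and sorted per chromosome.
#'
#' @param path TSV/BED path (no header, or a header line with non-numeric
#'   second field, which is skipped).
#' @param mark Histone modification name for the track.
#' @return A [nucleosome_track()] object.
#' @export
read_nucleosome_track <- function(path, mark) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2])))
  df <- read.table(path, sep = "\t", header = has_header,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("track file needs at least 2 columns: ", path)
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) | x != floor(x))
    if (length(bad))
      stop(sprintf("non-integer %s at line %d of %s", what,
                   bad[1] + has_header, path))
    x
  }
  if (ncol(df) == 2L) {
    center <- num(2L, "center coordinate")
  } else {
    start <- num(2L, "start coordinate")
    end <- num(3L, "end coordinate")
    center <- (start + end) %/% 2
  }
  nucleosome_track(mark, df[[1L]], center)
}

# format a numeric column at fixed 6 decimals; integers pass through
.fmt_col <- function(x) {
  if (is.numeric(x) && !is.integer(x) && any(x != floor(x), na.rm = TRUE))
    sprintf("%.6f", x)
  else x
}

#' Write scored intervals as TSV
#'
#' Fixed column order (chrom, start, end, label, features..., pwm_score,
#' lrc_proba, combined_score, flags as available), deterministic row order
#' (chrom, start) and floats at 6 decimals, so two identical runs produce
#' byte-identical files.
#'
#' @param intervals data.frame from [build_test_set()] /
#'   [transfer_predict()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(intervals, path) {
  df <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  lead <- intersect(c("chrom", "start", "end", "label"), names(df))
  tailc <- intersect(c("pwm_score", "lrc_proba", "combined_score", "flags"),
                     names(df))
  mid <- setdiff(names(df), c(lead, tailc))
  df <- df[, c(lead, mid, tailc), drop = FALSE]
  out <- as.data.frame(lapply(df, .fmt_col), stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scores TSV written by [write_scores()]
#' @param path Input path.
#' @return data.frame.
#' @export
read_scores <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = NA)
}

#' Write a training set's features as TSV
#' @param train A `training_set` from [build_training_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(train, path) {
  df <- cbind(train$anchors, as.data.frame(train$X))
  out <- as.data.frame(lapply(df, .fmt_col), stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve a pipeline configuration
#'
#' Fills defaults and validates keys. Accepted keys (with defaults):
#' `data_dir` (NULL: simulate), `simulate` (list of [synthetic_spec()]
#' overrides), `tf_name` ("SynTF"), `train_chrom` ("chr1"), `mode` ("mnn"),
#' `marks` (NULL: all tracks), `bin_size` (1000), `flank` (1000),
#' `footprint` (15), `pseudocount` ("sqrt_n"), `combine` ("product"),
#' `combine_weight` (0.5), `negative_ratio` (2), `lambda` (0), `seed` (1).
#' Unknown keys are rejected.
#'
#' @param config A list of overrides or a path to a YAML file.
#' @return A complete configuration list.
#' @export
read_run_config <- function(config = list()) {
  defaults <- list(data_dir = NULL, simulate = NULL, tf_name = "SynTF",
                   train_chrom = "chr1", mode = "mnn", marks = NULL,
                   bin_size = 1000L, flank = 1000L, footprint = 15L,
                   pseudocount = "sqrt_n", combine = "product",
                   combine_weight = 0.5, negative_ratio = 2L, lambda = 0,
                   seed = 1L)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML path")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  if (!cfg$mode %in% c("mnn", "mno")) stop("mode must be 'mnn' or 'mno'")
  if (!cfg$combine %in% c("product", "loglinear"))
    stop("combine must be 'product' or 'loglinear'")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
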