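# Position weight matrix: pseudocount-smoothed frequencies against a
# zero-order background, log2 log-odds, and a relative [0,1] unit scale
# anchored at the column-min and column-max score sums.

#' Build a position weight matrix from aligned binding-site sequences
#'
#' Counts nucleotides per position over `sites`, adds background-proportional
#' pseudocounts, and converts to frequencies and log2 odds against a
#' zero-order background model:
#' \deqn{f_{b,i} = (c_{b,i} + p_b) / (N + P), \qquad
#'       m_{b,i} = \log_2(f_{b,i} / q_b)}
#' where \eqn{c_{b,i}} are the observed counts, \eqn{N} the number of sites,
#' \eqn{P} the total pseudocount (default \eqn{\sqrt N}) distributed
#' proportionally to the background as \eqn{p_b = P q_b}. The column-wise
#' minimum and maximum score sums `s_min` and `s_max` anchor the relative
#' unit scale used by [scale_score()].
#'
#' @param sites Character vector of equal-length DNA strings (A/C/G/T only).
#'   Sites taken from the minus strand must be reverse-complemented by the
#'   caller before counting (see [extract_site_sequences()]).
#' @param background Numeric length-4 background frequencies (A, C, G, T),
#'   summing to 1. Default uniform.
#' @param pseudocount_total Total pseudocount \eqn{P}: the string `"sqrt_n"`
#'   (default, \eqn{P=\sqrt N}) or a positive number.
#' @return Object of class `pwm`: list with `freq` and `logodds` (4 x L
#'   matrices, rows A,C,G,T), `background`, `s_min`, `s_max`, `n_sites`,
#'   `length`, `pseudocount_total`.
#' @export
#' @examples
#' p <- build_pwm(c("TATAAT", "TATAAT", "TATGAT", "TACAAT"))
#' p
#' scale_score(p, score_subsequence(p, "TATAAT"))
build_pwm <- function(sites, background = rep(0.25, 4),
                      pseudocount_total = "sqrt_n") {
  if (length(sites) < 1L) stop("need at least one site sequence")
  L <- unique(nchar(sites))
  if (length(L) != 1L)
    stop("all site sequences must have equal length (got lengths ",
         paste(sort(L), collapse = ", "), ")")
  if (L < 1L) stop("site sequences must be non-empty")
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("'background' must be 4 positive frequencies summing to 1")
  background <- as.numeric(background)

  counts <- matrix(0, nrow = 4L, ncol = L,
                   dimnames = list(.DNA_BASES, NULL))
  for (k in seq_along(sites)) {
    codes <- .dna_codes(sites[[k]])
    if (anyNA(codes)) {
      j <- which(is.na(codes))[1L]
      stop(sprintf("non-ACGT character '%s' in site %d at position %d",
                   substr(sites[[k]], j, j), k, j))
    }
    counts[cbind(codes, seq_len(L))] <- counts[cbind(codes, seq_len(L))] + 1
  }

  N <- length(sites)
  P <- if (identical(pseudocount_total, "sqrt_n")) sqrt(N)
       else if (is.numeric(pseudocount_total) && pseudocount_total > 0)
         as.numeric(pseudocount_total)
       else stop("'pseudocount_total' must be \"sqrt_n\" or a positive number")
  pb <- P * background

  freq <- (counts + pb) / (N + P)
  logodds <- log2(freq / background)
  s_min <- sum(apply(logodds, 2L, min))
  s_max <- sum(apply(logodds, 2L, max))
  if (!(s_min < s_max))
    stop("degenerate PWM: s_min >= s_max")

  structure(list(freq = freq, logodds = logodds, background = background,
                 s_min = s_min, s_max = s_max, n_sites = N, length = L,
                 pseudocount_total = P),
            class = "pwm")
}

#' @export
print.pwm <- function(x, digits = 3, ...) {
  cat(sprintf("<pwm> length %d, built from %d sites (pseudocount P = %.3g)\n",
              x$length, x$n_sites, x$pseudocount_total))
  cat(sprintf("  consensus: %s\n  s_min = %.4f, s_max = %.4f\n",
              pwm_consensus(x), x$s_min, x$s_max))
  invisible(x)
}

#' Consensus sequence of a PWM (column-max base at each position)
#' @param pwm A [build_pwm()] object.
#' @return Character string of length `pwm$length`.
#' @export
pwm_consensus <- function(pwm) {
  paste(.DNA_BASES[apply(pwm$logodds, 2L, which.max)], collapse = "")
}

#' Raw log-odds score of a sequence exactly matching the PWM length
#'
#' Sums the per-position log2-odds matrix entries. Sequences containing
#' non-ACGT characters are unscorable and yield `NA`.
#'
#' @param pwm A [build_pwm()] object.
#' @param seq DNA string of length `pwm$length`.
#' @return Raw log-odds score, or `NA_real_` if the sequence contains an
#'   ambiguous base.
#' @export
score_subsequence <- function(pwm, seq) {
  if (nchar(seq) != pwm$length)
    stop(sprintf("sequence length %d does not match PWM length %d",
                 nchar(seq), pwm$length))
  codes <- .dna_codes(seq)
  if (anyNA(codes)) return(NA_real_)
  sum(pwm$logodds[cbind(codes, seq_len(pwm$length))])
}

#' Convert a raw log-odds score to the relative unit scale
#'
#' Maps `s_min -> 0` and `s_max -> 1` linearly:
#' `(raw - s_min) / (s_max - s_min)`. The result is clipped to `[0, 1]`
#' only to absorb floating-point drift; any ACGT sequence's raw score lies
#' within `[s_min, s_max]` by construction. The relative score is invariant
#' to the logarithm base used for the log-odds.
#'
#' @param pwm A [build_pwm()] object.
#' @param raw Raw log-odds score(s); `NA` passes through.
#' @return Relative score(s) in `[0, 1]`.
#' @export
scale_score <- function(pwm, raw) {
  if (!(pwm$s_max > pwm$s_min)) stop("degenerate PWM: s_max <= s_min")
  pmin(1, pmax(0, (raw - pwm$s_min) / (pwm$s_max - pwm$s_min)))
}

# Scaled best-of-both-strands score at every window start of a code vector.
# Returns a vector over window starts 1..(n-L+1); NA where the window
# contains an ambiguous base on both strands (i.e. any ambiguous base).
.window_scores <- function(pwm, codes) {
  L <- pwm$length
  n <- length(codes)
  W <- n - L + 1L
  if (W < 1L) return(numeric(0))
  m <- pwm$logodds
  # reverse-complement matrix: scoring a forward window with mrc equals
  # scoring its reverse complement with m (complement: A<->T, C<->G = 5-b)
  mrc <- m[4:1, L:1, drop = FALSE]
  fwd <- numeric(W)
  rev <- numeric(W)
  for (i in seq_len(L)) {
    idx <- codes[i:(i + W - 1L)]
    fwd <- fwd + m[(i - 1L) * 4L + idx]
    rev <- rev + mrc[(i - 1L) * 4L + idx]
  }
  scale_score(pwm, pmax(fwd, rev))
}

#' Best PWM score of a genomic interval over both strands
#'
#' Scores every length-L window fully contained in `[start, end)` on the
#' forward strand and as its reverse complement, and returns the maximum
#' relative score. Windows containing ambiguous bases are skipped; if no
#' scorable window exists the interval scores 0 (worst relative score).
#'
#' @param pwm A [build_pwm()] object.
#' @param seq Chromosome sequence (single string).
#' @param start,end 0-based half-open interval within the chromosome.
#' @return Relative score in `[0, 1]`.
#' @export
score_interval <- function(pwm, seq, start, end) {
  n <- nchar(seq)
  if (start < 0 || end > n || start >= end)
    stop("interval out of chromosome bounds")
  if (end - start < pwm$length)
    stop(sprintf("interval [%d,%d) shorter than PWM length %d",
                 start, end, pwm$length))
  s <- .window_scores(pwm, .dna_codes(substr(seq, start + 1L, end)))
  if (all(is.na(s))) return(0)
  max(s, na.rm = TRUE)
}

#' Scan a chromosome in fixed-width bins with a PWM
#'
#' Bins the chromosome with [bin_chromosome()] and assigns each bin its best
#' double-strand relative PWM score over all windows fully inside the bin.
#'
#' @param pwm A [build_pwm()] object.
#' @param seq Chromosome sequence (single string).
#' @param chrom Chromosome name for the output.
#' @param bin_size Bin width in bp (default 1000; must be >= PWM length).
#' @return data.frame: `chrom`, `start`, `end`, `pwm_score`, and logical
#'   `unscorable` flagging bins with no ambiguity-free window (scored 0).
#' @export
scan_bins <- function(pwm, seq, chrom = "chr1", bin_size = 1000L) {
  L <- pwm$length
  if (bin_size < L) stop("'bin_size' must be at least the PWM length")
  bins <- bin_chromosome(nchar(seq), bin_size)
  if (nrow(bins) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), pwm_score = numeric(0),
                      unscorable = logical(0)))
  s <- .window_scores(pwm, .dna_codes(seq))  # index j+1 = window start j
  score <- numeric(nrow(bins))
  unscor <- logical(nrow(bins))
  for (b in seq_len(nrow(bins))) {
    w <- s[(bins$start[b] + 1L):(bins$end[b] - L + 1L)]
    if (all(is.na(w))) {
      score[b] <- 0
      unscor[b] <- TRUE
    } else {
      score[b] <- max(w, na.rm = TRUE)
    }
  }
  data.frame(chrom = chrom, start = bins$start, end = bins$end,
             pwm_score = score, unscorable = unscor,
             stringsAsFactors = FALSE)
}

#' Extract binding-site sequences from a genome
#'
#' Pulls the sequence of each site interval; minus-strand sites are
#' reverse-complemented so all returned sequences read in motif orientation.
#'
#' @param sites A [binding_sites()] object.
#' @param genome Named character vector of chromosome sequences.
#' @return Character vector of site sequences.
#' @export
extract_site_sequences <- function(sites, genome) {
  missing <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  seqs <- character(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    s <- substr(genome[[sites$chrom[k]]], sites$start[k] + 1L, sites$end[k])
    seqs[k] <- if (sites$strand[k] == "-") revcomp(s) else s
  }
  seqs
}

#' Write a PWM to disk
#'
#' `format = "json"` (default) writes a single JSON document holding the
#' frequency matrix, background, pseudocount configuration and scale
#' anchors; `format = "jaspar"` writes the frequency matrix as plain-text
#' 4-row counts (A/C/G/T) with a JSON sidecar `<path>.meta.json` for the
#' background and scale anchors.
#'
#' @param pwm A [build_pwm()] object.
#' @param path Output path.
#' @param format "json" or "jaspar".
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path, format = c("json", "jaspar")) {
  format <- match.arg(format)
  meta <- list(background = pwm$background, s_min = pwm$s_min,
               s_max = pwm$s_max, n_sites = pwm$n_sites,
               pseudocount_total = pwm$pseudocount_total,
               format_version = 1L)
  if (format == "json") {
    obj <- c(list(freq = pwm$freq), meta)
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                         matrix = "rowmajor")
  } else {
    rows <- vapply(seq_len(4L), function(b)
      sprintf("%s  [ %s ]", .DNA_BASES[b],
              paste(sprintf("%.10g", pwm$freq[b, ]), collapse = " ")),
      character(1))
    writeLines(rows, path)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = I(17),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a PWM written by [write_pwm()] (JSON format)
#' @param path Path to the JSON file.
#' @return A `pwm` object.
#' @export
read_pwm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  freq <- matrix(as.numeric(obj$freq), nrow = 4L,
                 dimnames = list(.DNA_BASES, NULL), byrow = FALSE)
  # rowmajor written matrices come back as a 4xL numeric matrix already
  if (is.matrix(obj$freq)) freq <- obj$freq
  dimnames(freq) <- list(.DNA_BASES, NULL)
  logodds <- log2(freq / obj$background)
  structure(list(freq = freq, logodds = logodds,
                 background = as.numeric(obj$background),
                 s_min = obj$s_min, s_max = obj$s_max,
                 n_sites = obj$n_sites, length = ncol(freq),
                 pseudocount_total = obj$pseudocount_total),
            class = "pwm")
}
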