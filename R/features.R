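# Epigenetic features at an anchor position: MNN (distance to the nearest
# modified-nucleosome center of a mark) and MNO (count of centers within a
# flanking window), plus nucleosome-distribution profiles around sites.

# nearest |center - pos| on a sorted integer vector, vectorized over pos
.nearest_dist <- function(centers, pos) {
  n <- length(centers)
  idx <- findInterval(pos, centers)
  dl <- ifelse(idx >= 1L, pos - centers[pmax(idx, 1L)], Inf)
  dr <- ifelse(idx < n, centers[pmin(idx + 1L, n)] - pos, Inf)
  pmin(dl, dr)
}

# count of centers in closed window [pos - flank, pos + flank]
.count_in_window <- function(centers, pos, flank) {
  findInterval(pos + flank + 0.5, centers) -
    findInterval(pos - flank - 0.5, centers)
}

#' Distance to the nearest modified-nucleosome center (MNN)
#'
#' Absolute distance (bp) from each anchor position to the nearest
#' nucleosome center of the track's mark on the same chromosome. Equidistant
#' left/right neighbors share the same minimal value by definition.
#'
#' @param track A [nucleosome_track()] object.
#' @param chrom Chromosome name (single string).
#' @param pos Anchor position(s), 0-based bp.
#' @return Numeric vector of non-negative distances.
#' @export
nearest_nucleosome_distance <- function(track, chrom, pos) {
  centers <- track$centers[[chrom]]
  if (is.null(centers) || length(centers) == 0L)
    stop(sprintf("no nucleosomes of mark %s on chromosome %s",
                 track$mark, chrom))
  .nearest_dist(centers, pos)
}

#' Count of modified nucleosomes flanking an anchor (MNO)
#'
#' Number of nucleosome centers within the closed window
#' `[pos - flank, pos + flank]` (a 2-kb window at the default flank).
#' An empty track or absent chromosome yields 0.
#'
#' @inheritParams nearest_nucleosome_distance
#' @param flank Flank half-width in bp (> 0, default 1000).
#' @return Integer vector of counts.
#' @export
occupancy_count <- function(track, chrom, pos, flank = 1000L) {
  if (flank <= 0) stop("'flank' must be positive")
  centers <- track$centers[[chrom]]
  if (is.null(centers) || length(centers) == 0L)
    return(rep(0L, length(pos)))
  as.integer(.count_in_window(centers, pos, flank))
}

# shared worker: per-mark feature matrix at anchors; `fun` is the scalar op.
.feature_matrix <- function(tracks, chrom, pos, mode, flank, sentinel = NULL) {
  marks <- vapply(tracks, `[[`, character(1), "mark")
  X <- matrix(NA_real_, nrow = length(pos), ncol = length(tracks),
              dimnames = list(NULL, paste0(mode, "_", marks)))
  sentinel_used <- logical(length(tracks))
  for (j in seq_along(tracks)) {
    if (mode == "mnn") {
      centers <- tracks[[j]]$centers[[chrom]]
      if (is.null(centers) || length(centers) == 0L) {
        if (is.null(sentinel))
          stop(sprintf("no nucleosomes of mark %s on chromosome %s",
                       marks[j], chrom))
        warning(sprintf(
          "mark %s has no nucleosomes on %s; substituting sentinel distance %g",
          marks[j], chrom, sentinel))
        X[, j] <- sentinel
        sentinel_used[j] <- TRUE
      } else {
        X[, j] <- .nearest_dist(centers, pos)
      }
    } else {
      X[, j] <- occupancy_count(tracks[[j]], chrom, pos, flank)
    }
  }
  attr(X, "sentinel_used") <- sentinel_used
  X
}

#' Per-mark MNN feature vector at one anchor
#'
#' Applies [nearest_nucleosome_distance()] per mark, in the order the tracks
#' are given (use canonical [histone_marks()] order for the full set).
#'
#' @param tracks List of [nucleosome_track()] objects.
#' @param chrom Chromosome name.
#' @param pos Anchor position (0-based bp).
#' @return Named numeric vector (names `mnn_<mark>`).
#' @export
mnn_vector <- function(tracks, chrom, pos) {
  stopifnot(length(pos) == 1L)
  X <- .feature_matrix(tracks, chrom, pos, "mnn", flank = NULL)
  setNames(X[1L, ], colnames(X))
}

#' Per-mark MNO feature vector at one anchor
#'
#' @inheritParams mnn_vector
#' @param flank Flank half-width in bp (default 1000).
#' @return Named numeric vector (names `mno_<mark>`).
#' @export
mno_vector <- function(tracks, chrom, pos, flank = 1000L) {
  stopifnot(length(pos) == 1L)
  X <- .feature_matrix(tracks, chrom, pos, "mno", flank = flank)
  setNames(X[1L, ], colnames(X))
}

#' Nucleosome-distribution profile around binding sites
#'
#' For every binding site and every nucleosome center within
#' `half_window + footprint` bp of the site center, the positions from
#' `-footprint` to `+footprint` around the nucleosome center are taken as
#' positions where the nucleosome exists; occupancy is accumulated at each
#' offset relative to the site center and divided by the number of binding
#' sites. With the defaults the offsets span -1015..+1015 bp and each
#' nucleosome contributes a 31-bp footprint.
#'
#' @param track A [nucleosome_track()] object.
#' @param sites A [binding_sites()] object (>= 1 site).
#' @param half_window Half-width of the window around site centers (bp,
#'   default 1000).
#' @param footprint Half-width of the nucleosome footprint (bp, default 15).
#' @return Object of class `position_profile`: data.frame with `offset`
#'   (-W..W, W = half_window + footprint) and `ratio` (occupancy count over
#'   number of sites); attributes `mark` and `n_sites`.
#' @export
position_profile <- function(track, sites, half_window = 1000L,
                             footprint = 15L) {
  if (!inherits(sites, "binding_sites") || nrow(sites) == 0L)
    stop("'sites' must be a non-empty binding_sites object")
  W <- as.integer(half_window + footprint)
  diffv <- numeric(2L * W + 2L)
  ia_all <- integer(0)
  ib_all <- integer(0)
  for (ch in unique(sites$chrom)) {
    centers <- track$centers[[ch]]
    if (is.null(centers) || length(centers) == 0L) next
    for (s in sites$center[sites$chrom == ch]) {
      lo <- findInterval(s - W - 0.5, centers) + 1L
      hi <- findInterval(s + W + 0.5, centers)
      if (hi < lo) next
      d <- centers[lo:hi] - s
      a <- pmax(d - footprint, -W)
      b <- pmin(d + footprint, W)
      ia_all <- c(ia_all, a + W + 1L)
      ib_all <- c(ib_all, b + W + 2L)
    }
  }
  nb <- 2L * W + 2L
  diffv <- tabulate(ia_all, nbins = nb) - tabulate(ib_all, nbins = nb)
  counts <- cumsum(diffv)[seq_len(2L * W + 1L)]
  out <- data.frame(offset = seq(-W, W), ratio = counts / nrow(sites))
  attr(out, "mark") <- track$mark
  attr(out, "n_sites") <- nrow(sites)
  class(out) <- c("position_profile", "data.frame")
  out
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf(
    "<position_profile> mark %s over %d sites; offsets %d..%d, peak ratio %.4g\n",
    attr(x, "mark"), attr(x, "n_sites"), min(x$offset), max(x$offset),
    max(x$ratio)))
  invisible(x)
}

#' @export
plot.position_profile <- function(x, ...) {
  plot(x$offset, x$ratio, type = "l",
       xlab = "offset from site center (bp)",
       ylab = "nucleosomes per site",
       main = sprintf("%s around binding sites", attr(x, "mark")), ...)
  abline(v = 0, lty = 3)
  invisible(x)
}
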