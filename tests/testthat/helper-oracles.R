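# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code path with the package internals.

random_dna <- function(n, p_n = 0) {
  bases <- c("A", "C", "G", "T")
  x <- sample(bases, n, replace = TRUE)
  if (p_n > 0) x[runif(n) < p_n] <- "N"
  paste(x, collapse = "")
}

chars_of <- function(seq) strsplit(seq, "")[[1]]

revcomp_chars <- function(ch) {
  rev(unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch]))
}

# raw log-odds of a window by explicit per-character lookup
brute_raw_score <- function(pwm, window_chars) {
  if (any(!window_chars %in% c("A", "C", "G", "T"))) return(NA_real_)
  sum(vapply(seq_along(window_chars), function(i)
    pwm$logodds[window_chars[i], i], numeric(1)))
}

# max scaled double-strand score over all windows of seq[start..end) by
# explicit enumeration (0-based half-open coordinates)
brute_interval_score <- function(pwm, seq, start, end) {
  ch <- chars_of(seq)
  L <- pwm$length
  best <- -Inf
  for (j in start:(end - L)) {
    w <- ch[(j + 1):(j + L)]
    for (raw in c(brute_raw_score(pwm, w),
                  brute_raw_score(pwm, revcomp_chars(w)))) {
      if (!is.na(raw)) {
        rel <- (raw - pwm$s_min) / (pwm$s_max - pwm$s_min)
        if (rel > best) best <- rel
      }
    }
  }
  if (is.infinite(best)) 0 else best
}

# nearest-distance by linear scan
brute_nearest <- function(centers, pos) {
  vapply(pos, function(p) min(abs(centers - p)), numeric(1))
}

# occupancy by linear scan over a closed window
brute_occupancy <- function(centers, pos, flank) {
  vapply(pos, function(p) sum(centers >= p - flank & centers <= p + flank),
         numeric(1))
}

# profile by triple loop over (site, nucleosome, offset)
brute_profile <- function(centers, site_centers, half_window, footprint) {
  W <- half_window + footprint
  counts <- setNames(numeric(2 * W + 1), seq(-W, W))
  for (s in site_centers) {
    for (cc in centers) {
      d <- cc - s
      if (abs(d) <= W) {
        for (o in max(d - footprint, -W):min(d + footprint, W))
          counts[as.character(o)] <- counts[as.character(o)] + 1
      }
    }
  }
  unname(counts) / length(site_centers)
}

# AUC as the Mann-Whitney pairwise statistic with half credit for ties
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# central finite-difference gradient of the cost
fd_gradient <- function(theta, X, y, lambda = 0, h = 1e-5) {
  vapply(seq_along(theta), function(k) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (lrc_cost(tp, X, y, lambda)$J - lrc_cost(tm, X, y, lambda)$J) / (2 * h)
  }, numeric(1))
}

# small deterministic dataset shared by pipeline-level tests
small_spec <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2L, chrom_length = 2e5, n_sites = 40L,
         seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}
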