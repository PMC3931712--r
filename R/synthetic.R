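# Synthetic dataset generator: random genome with planted motif instances,
# binding-site GFF, and per-mark nucleosome-center tracks. Active marks are
# placed as a two-Gaussian mixture at +/- peak_offset around site centers
# with a central exclusion zone (the nucleosome-free region), on top of a
# sparse uniform background; repressive and moderate marks are uniform
# background only.

#' Specification of a synthetic dataset
#'
#' Defaults describe a desk-scale study: 3 chromosomes of 2 Mb, 500 planted
#' sites per chromosome, bimodal active-mark enrichment (peaks at +/-150 bp,
#' sd 50 bp, nucleosome-free zone +/-40 bp) and one 20-kb assembly gap per
#' chromosome. The per-class background densities (active 0.1, moderate 1,
#' repressive 5 nucleosome centers per kb) reflect that active-methylation
#' nucleosomes are sparse outside regulatory regions while repressive marks
#' blanket heterochromatin at near-full nucleosome density.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param gc_content Genome GC fraction.
#' @param motif_consensus Planted motif consensus (A/C/G/T string).
#' @param mutation_rate Per-position probability that a planted instance
#'   deviates from the consensus.
#' @param n_sites Planted sites per chromosome.
#' @param tf_name Factor name written to the GFF.
#' @param marks data.frame with columns `mark`, `class`
#'   (active/moderate/repressive).
#' @param peak_offset Distance of the two enrichment peaks from the site
#'   center (bp).
#' @param peak_sd Peak standard deviation (bp); offsets are truncated at
#'   `peak_offset + 4 * peak_sd`.
#' @param center_depletion Half-width of the nucleosome-free exclusion zone
#'   around site centers (bp); must be smaller than `peak_offset`.
#' @param nuc_per_site Enriched nucleosomes placed per site for each active
#'   mark (0 switches enrichment off).
#' @param bg_rate_active,bg_rate_moderate,bg_rate_repressive Uniform
#'   background density per class (nucleosome centers per kb).
#' @param gap_runs List of `c(start, length)` N-runs stamped into every
#'   chromosome; default: one run of 1% of the chromosome (at least 2 kb)
#'   starting at 60% of its length.
#' @param seed RNG seed; a fixed seed makes [generate_dataset()] output
#'   byte-identical.
#' @return Object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_chromosomes = 3L,
                           chrom_length = 2e6,
                           gc_content = 0.41,
                           motif_consensus = "TGACGTCATGCA",
                           mutation_rate = 0.15,
                           n_sites = 500L,
                           tf_name = "SynTF",
                           marks = data.frame(
                             mark = c("H3K4me3", "H2A.Z", "H3K4me1",
                                      "H3K9me3"),
                             class = c("active", "active", "active",
                                       "repressive"),
                             stringsAsFactors = FALSE),
                           peak_offset = 150,
                           peak_sd = 50,
                           center_depletion = 40,
                           nuc_per_site = 6L,
                           bg_rate_active = 0.1,
                           bg_rate_moderate = 1,
                           bg_rate_repressive = 5,
                           gap_runs = NULL,
                           seed = 1L) {
  if (is.null(gap_runs))
    gap_runs <- list(c(round(0.6 * chrom_length),
                       max(2000, round(0.01 * chrom_length))))
  spec <- list(n_chromosomes = as.integer(n_chromosomes),
               chrom_length = as.integer(chrom_length),
               gc_content = gc_content,
               motif_consensus = toupper(motif_consensus),
               mutation_rate = mutation_rate,
               n_sites = as.integer(n_sites),
               tf_name = tf_name, marks = marks,
               peak_offset = peak_offset, peak_sd = peak_sd,
               center_depletion = center_depletion,
               nuc_per_site = as.integer(nuc_per_site),
               bg_rate_active = bg_rate_active,
               bg_rate_moderate = bg_rate_moderate,
               bg_rate_repressive = bg_rate_repressive,
               gap_runs = gap_runs, seed = as.integer(seed))
  if (spec$n_chromosomes < 1L || spec$chrom_length < 1L)
    stop("need at least one chromosome of positive length")
  if (anyNA(.dna_codes(spec$motif_consensus)))
    stop("'motif_consensus' must be an A/C/G/T string")
  if (spec$gc_content <= 0 || spec$gc_content >= 1)
    stop("'gc_content' must be in (0, 1)")
  if (spec$mutation_rate < 0 || spec$mutation_rate > 1)
    stop("'mutation_rate' must be in [0, 1]")
  rates <- c(spec$bg_rate_active, spec$bg_rate_moderate,
             spec$bg_rate_repressive)
  if (any(rates < 0) || spec$nuc_per_site < 0)
    stop("rates and per-site counts must be non-negative")
  if (spec$center_depletion >= spec$peak_offset)
    stop("'center_depletion' must be smaller than 'peak_offset'")
  if (!all(spec$marks$class %in% c("active", "moderate", "repressive")))
    stop("mark classes must be active/moderate/repressive")
  for (g in spec$gap_runs)
    if (length(g) != 2L || g[1] < 0 || g[2] <= 0 ||
        g[1] + g[2] > spec$chrom_length)
      stop("each gap run must be c(start, length) inside the chromosome")
  class(spec) <- "synthetic_spec"
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_spec> %d x %.2g-Mb chromosome(s), %d sites each ",
    "(motif %s)\n  active marks: peaks +/-%g bp (sd %g), depletion +/-%g, ",
    "%d nucleosomes/site, bg %g/kb\n  marks: %s; seed %d\n"),
    x$n_chromosomes, x$chrom_length / 1e6, x$n_sites, x$motif_consensus,
    x$peak_offset, x$peak_sd, x$center_depletion, x$nuc_per_site,
    x$bg_rate_active,
    paste(sprintf("%s(%s)", x$marks$mark, x$marks$class), collapse = ", "),
    x$seed))
  invisible(x)
}

# uniform positions in non-gapped regions, length-weighted across runs
.sample_nongap <- function(regions, n) {
  if (n == 0L) return(integer(0))
  w <- regions$end - regions$start
  ridx <- sample.int(nrow(regions), n, replace = TRUE, prob = w)
  as.integer(regions$start[ridx] + floor(runif(n) * w[ridx]))
}

# bimodal offsets: side +/- peak_offset + N(0, sd), truncated to
# depletion < |offset| <= peak_offset + 4 sd
.bimodal_offsets <- function(n, mu, sd, depl) {
  out <- numeric(0)
  while (length(out) < n) {
    k <- max(2L * (n - length(out)), 16L)
    o <- sample(c(-1, 1), k, replace = TRUE) * mu + rnorm(k, 0, sd)
    o <- o[abs(o) > depl & abs(o) <= mu + 4 * sd]
    out <- c(out, o)
  }
  round(out[seq_len(n)])
}

#' Generate a synthetic dataset on disk
#'
#' Writes `genome.fa` (chromosomes with planted motif instances and N-run
#' gaps), `sites.gff` (planted sites, 1-based GFF3), `tracks/<mark>.tsv`
#' (chrom + center per nucleosome), a truth table
#' `truth_sites.tsv` and the spec itself (`spec.json`). All randomness
#' derives from `spec$seed`; regenerating with the same spec yields
#' byte-identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory `genome`, `sites`, `tracks`
#'   and the written `paths`.
#' @export
generate_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  dir.create(file.path(dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  L <- nchar(spec$motif_consensus)
  cons_codes <- .dna_codes(spec$motif_consensus)
  base_prob <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
                 spec$gc_content / 2, (1 - spec$gc_content) / 2)

  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  genome <- character(0)
  site_rows <- list()
  track_pos <- lapply(seq_len(nrow(spec$marks)),
                      function(i) list(chrom = character(0),
                                       center = integer(0)))

  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n <- spec$chrom_length
    codes <- sample.int(4L, n, replace = TRUE, prob = base_prob)
    gap_mask <- logical(n)
    for (g in spec$gap_runs)
      gap_mask[(g[1] + 1):(g[1] + g[2])] <- TRUE

    # eligible motif start coords: clear of gaps and >= L from both the
    # chromosome edges and any gap edge; a 2-kb margin keeps full flanking
    # windows on real sequence
    margin <- max(2000L, L)
    ok <- !gap_mask
    for (g in spec$gap_runs) {
      lo <- max(1L, g[1] + 1L - margin)
      hi <- min(n, g[1] + g[2] + margin)
      ok[lo:hi] <- FALSE
    }
    ok[seq_len(margin)] <- FALSE
    ok[(n - margin - L):n] <- FALSE
    eligible <- which(ok)

    starts <- integer(0)
    tries <- 0L
    while (length(starts) < spec$n_sites) {
      tries <- tries + 1L
      if (tries > 50L)
        stop("could not place ", spec$n_sites,
             " non-overlapping sites; reduce density")
      cand <- sort(sample(eligible, spec$n_sites * 2L))
      cand <- cand[c(TRUE, diff(cand) >= L)]
      starts <- sort(unique(c(starts, cand)))
      starts <- starts[c(TRUE, diff(starts) >= L)]
    }
    starts <- sort(sample(starts, spec$n_sites))
    strands <- sample(c("+", "-"), spec$n_sites, replace = TRUE)

    for (k in seq_len(spec$n_sites)) {
      inst <- cons_codes
      mut <- runif(L) < spec$mutation_rate
      if (any(mut))
        inst[mut] <- ((inst[mut] - 1L + sample.int(3L, sum(mut),
                                                   replace = TRUE)) %% 4L) + 1L
      if (strands[k] == "-") inst <- rev(5L - inst)
      codes[starts[k]:(starts[k] + L - 1L)] <- inst
    }

    seq_chars <- .DNA_BASES[codes]
    seq_chars[gap_mask] <- "N"
    genome[[ch]] <- paste(seq_chars, collapse = "")

    start0 <- starts - 1L  # to 0-based
    site_rows[[ci]] <- data.frame(
      chrom = ch, start = start0, end = start0 + L, strand = strands,
      center = interval_center(start0, start0 + L),
      stringsAsFactors = FALSE)

    nongap <- nongap_regions(genome[[ch]], min_len = 1L)
    centers <- site_rows[[ci]]$center
    for (mi in seq_len(nrow(spec$marks))) {
      cls <- spec$marks$class[mi]
      bg_rate <- switch(cls, active = spec$bg_rate_active,
                        moderate = spec$bg_rate_moderate,
                        repressive = spec$bg_rate_repressive)
      pos <- .sample_nongap(nongap, rpois(1L, bg_rate * n / 1000))
      if (cls == "active" && spec$nuc_per_site > 0L) {
        offs <- .bimodal_offsets(spec$n_sites * spec$nuc_per_site,
                                 spec$peak_offset, spec$peak_sd,
                                 spec$center_depletion)
        enriched <- rep(centers, each = spec$nuc_per_site) + offs
        enriched <- enriched[enriched >= 0L & enriched < n]
        pos <- c(pos, as.integer(enriched))
      }
      track_pos[[mi]]$chrom <- c(track_pos[[mi]]$chrom,
                                 rep(ch, length(pos)))
      track_pos[[mi]]$center <- c(track_pos[[mi]]$center, pos)
    }
  }

  sites <- do.call(rbind, site_rows)
  sites_obj <- binding_sites(sites$chrom, sites$start, sites$end,
                             sites$strand, tf_name = spec$tf_name)

  paths <- list(genome = file.path(dir, "genome.fa"),
                sites = file.path(dir, "sites.gff"),
                truth = file.path(dir, "truth_sites.tsv"),
                spec = file.path(dir, "spec.json"),
                tracks = file.path(dir, "tracks",
                                   paste0(spec$marks$mark, ".tsv")))

  write_genome_fasta(genome, paths$genome)
  write_gff_sites(sites_obj, paths$sites, source = "epimotif_sim")
  write.table(as.data.frame(sites_obj), paths$truth, sep = "\t",
              quote = FALSE, row.names = FALSE)
  sp <- unclass(spec)
  sp$gap_runs <- lapply(sp$gap_runs, as.numeric)
  jsonlite::write_json(sp, paths$spec, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns")

  tracks <- vector("list", nrow(spec$marks))
  for (mi in seq_len(nrow(spec$marks))) {
    tr <- nucleosome_track(spec$marks$mark[mi], track_pos[[mi]]$chrom,
                           track_pos[[mi]]$center)
    tracks[[mi]] <- tr
    df <- do.call(rbind, lapply(names(tr$centers), function(ch)
      data.frame(chrom = ch, center = tr$centers[[ch]],
                 stringsAsFactors = FALSE)))
    write.table(df, paths$tracks[mi], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  names(tracks) <- spec$marks$mark

  invisible(list(genome = genome, sites = sites_obj, tracks = tracks,
                 paths = paths, spec = spec))
}

#' Round-trip check of the generator against the profiler
#'
#' Computes [position_profile()] for each generated track against the truth
#' sites and reports, per mark: the offsets of the maximum ratio in the
#' negative and positive offset halves, whether the profile minimum over the
#' central +/- `peak_offset` region falls within +/-20 bp of offset 0 (the
#' nucleosome-free region), and the max/min ratio over the profile
#' (flatness). Active marks are expected to be bimodal with peaks near
#' +/- `peak_offset`; repressive marks to be flat (max/min < 1.5).
#'
#' @param dataset The list returned by [generate_dataset()].
#' @param half_window,footprint Profile parameters (defaults 1000, 15).
#' @return data.frame with one row per mark: `mark`, `class`,
#'   `peak_neg`, `peak_pos`, `center_min`, `flat_ratio`, `bimodal`, `flat`.
#' @export
profile_roundtrip_check <- function(dataset, half_window = 1000L,
                                    footprint = 15L) {
  spec <- dataset$spec
  out <- lapply(seq_len(nrow(spec$marks)), function(mi) {
    mark <- spec$marks$mark[mi]
    pr <- position_profile(dataset$tracks[[mark]], dataset$sites,
                           half_window, footprint)
    # smooth at the footprint scale so peak/valley locations reflect the
    # distribution, not single-offset counting noise
    sm <- stats::filter(pr$ratio, rep(1, 2L * footprint + 1L) /
                          (2L * footprint + 1L), sides = 2L)
    sm <- as.numeric(sm)
    ok <- !is.na(sm)
    off <- pr$offset[ok]
    sm <- sm[ok]
    peak_neg <- off[off < 0][which.max(sm[off < 0])]
    peak_pos <- off[off > 0][which.max(sm[off > 0])]
    # minimum location: the depleted center is a plateau of near-minimal
    # values, so take the median offset of the near-minimal set between
    # the two peaks
    ctr <- abs(off) <= spec$peak_offset
    thr <- min(sm[ctr]) + 0.05 * (max(sm) - min(sm[ctr]))
    min_loc <- stats::median(off[ctr][sm[ctr] <= thr])
    center_min <- abs(min_loc) <= 20
    # flatness of the smoothed profile over the fully-supported interior:
    # offsets beyond +/- half_window lose part of their 31-bp footprint
    # support at the window edge (a windowing artifact), and the same
    # footprint-scale smoothing as above keeps the statistic about the
    # distribution rather than per-offset counting noise
    interior <- sm[abs(off) <= half_window]
    flat_ratio <- max(interior) / max(min(interior), .Machine$double.eps)
    data.frame(mark = mark, class = spec$marks$class[mi],
               peak_neg = peak_neg, peak_pos = peak_pos,
               min_loc = min_loc, center_min = center_min,
               flat_ratio = flat_ratio,
               bimodal = abs(peak_neg + spec$peak_offset) <= 20 &&
                 abs(peak_pos - spec$peak_offset) <= 20 && center_min,
               flat = flat_ratio < 1.5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
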