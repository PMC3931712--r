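# Assembling training and test sets, combining classifier and PWM scores,
# and the end-to-end run.
#
# Deliberate asymmetry, preserved from the method's design: training
# features are computed at binding-SITE centers (and at sampled negative
# positions), while test features are computed at BIN centers.

# features at (chrom, pos) anchors spanning multiple chromosomes;
# sentinel_lengths: named chromosome lengths used as the substitute MNN
# distance when a mark has no nucleosome on a chromosome (NULL = error).
.features_at <- function(tracks, chrom, pos, mode, flank,
                         sentinel_lengths = NULL) {
  marks <- vapply(tracks, `[[`, character(1), "mark")
  X <- matrix(NA_real_, nrow = length(pos), ncol = length(tracks),
              dimnames = list(NULL, paste0(mode, "_", marks)))
  flags <- character(length(pos))
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    sentinel <- if (is.null(sentinel_lengths)) NULL else
      unname(sentinel_lengths[[ch]])
    Xc <- .feature_matrix(tracks, ch, pos[ix], mode, flank, sentinel)
    X[ix, ] <- Xc
    used <- attr(Xc, "sentinel_used")
    if (any(used))
      flags[ix] <- paste0("sentinel:",
                          paste(marks[used], collapse = ","))
  }
  attr(X, "flags") <- flags
  X
}

.select_tracks <- function(tracks, marks) {
  track_marks <- vapply(tracks, `[[`, character(1), "mark")
  if (is.null(marks)) return(tracks[order(match(track_marks,
                                                histone_marks()$mark))])
  miss <- setdiff(marks, track_marks)
  if (length(miss))
    stop("requested mark(s) without a track: ", paste(miss, collapse = ", "))
  tracks[match(marks, track_marks)]
}

#' Assemble the classifier training set from a training chromosome
#'
#' Positives are the feature vectors at binding-site centers; negatives are
#' feature vectors at `negative_ratio` (default 2) random positions per
#' positive, drawn uniformly from assembly-gap-free regions of the training
#' chromosome(s) (runs of A/C/G/T of at least 1 kb, so a full flanking
#' window of real sequence exists). `mode` selects MNN distances or MNO
#' counts for the requested mark subset.
#'
#' @param sites [binding_sites()] on the training chromosome(s).
#' @param tracks Named list of [nucleosome_track()] objects.
#' @param genome Named character vector of chromosome sequences (used for
#'   gap-aware negative sampling and the missing-mark sentinel).
#' @param mode `"mnn"` or `"mno"`.
#' @param marks Mark subset (default: all tracks, canonical order).
#' @param flank MNO flank half-width in bp (default 1000).
#' @param negative_ratio Negatives per positive (default 2).
#' @param seed RNG seed for the negative sample.
#' @return Object of class `training_set`: list with `X` (feature matrix),
#'   `y` (labels, 1 = binding region), `anchors` (data.frame chrom/pos/label),
#'   `mode`, `marks`, `seed`.
#' @export
build_training_set <- function(sites, tracks, genome, mode = c("mnn", "mno"),
                               marks = NULL, flank = 1000L,
                               negative_ratio = 2L, seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(sites, "binding_sites") || nrow(sites) == 0L)
    stop("'sites' must be a non-empty binding_sites object")
  tracks <- .select_tracks(tracks, marks)
  chroms <- unique(sites$chrom)
  lens <- vapply(genome, nchar, integer(1))

  regions <- do.call(rbind, lapply(chroms, function(ch) {
    if (!ch %in% names(genome))
      stop("chromosome absent from genome: ", ch)
    r <- nongap_regions(genome[[ch]], min_len = 1000L)
    if (nrow(r)) cbind(chrom = ch, r) else NULL
  }))
  if (is.null(regions) || nrow(regions) == 0L)
    stop("no non-gapped sequence of at least 1 kb to sample negatives from")

  m <- nrow(sites)
  n_neg <- as.integer(negative_ratio) * m
  set.seed(seed)
  w <- regions$end - regions$start
  ridx <- sample.int(nrow(regions), n_neg, replace = TRUE, prob = w)
  neg_pos <- regions$start[ridx] +
    floor(runif(n_neg) * (regions$end[ridx] - regions$start[ridx]))
  neg_chrom <- regions$chrom[ridx]

  chrom <- c(sites$chrom, neg_chrom)
  pos <- c(sites$center, as.integer(neg_pos))
  y <- c(rep(1L, m), rep(0L, n_neg))
  X <- .features_at(tracks, chrom, pos, mode, flank, sentinel_lengths = lens)
  structure(list(X = X, y = y,
                 anchors = data.frame(chrom = chrom, pos = pos, label = y,
                                      stringsAsFactors = FALSE),
                 mode = mode,
                 marks = vapply(tracks, `[[`, character(1), "mark"),
                 seed = seed),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %s features, %d marks, %d rows (%d positive)\n",
              toupper(x$mode), length(x$marks), length(x$y), sum(x$y)))
  invisible(x)
}

#' Bin test chromosomes and attach labels, features and PWM scores
#'
#' Every chromosome is cut into `bin_size` half-open bins; a bin is labeled
#' 1 when it contains the center of a reported binding site. Epigenetic
#' features are computed at the bin center; the PWM score (if a PWM is
#' given) is the best double-strand window score within the bin.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param sites [binding_sites()] (may include sites on non-test
#'   chromosomes; only test-chromosome sites label bins).
#' @param tracks Named list of [nucleosome_track()] objects.
#' @param pwm Optional [build_pwm()] object.
#' @param mode `"mnn"` or `"mno"`.
#' @param marks Mark subset (default all tracks).
#' @param test_chroms Chromosomes to bin (default: all of `genome`).
#' @param bin_size Bin width in bp (default 1000).
#' @param flank MNO flank (default 1000).
#' @return data.frame: `chrom`, `start`, `end`, `label`, feature columns
#'   (`mnn_*` or `mno_*`), `pwm_score` and `flags` (sentinel substitutions
#'   and unscorable bins, semicolon-separated).
#' @export
build_test_set <- function(genome, sites, tracks, pwm = NULL,
                           mode = c("mnn", "mno"), marks = NULL,
                           test_chroms = names(genome), bin_size = 1000L,
                           flank = 1000L) {
  mode <- match.arg(mode)
  tracks <- .select_tracks(tracks, marks)
  lens <- vapply(genome, nchar, integer(1))
  out <- vector("list", length(test_chroms))
  for (i in seq_along(test_chroms)) {
    ch <- test_chroms[i]
    if (!ch %in% names(genome)) stop("chromosome absent from genome: ", ch)
    bins <- bin_chromosome(lens[[ch]], bin_size)
    if (nrow(bins) == 0L) next
    centers <- sites$center[sites$chrom == ch]
    nhit <- .count_sites_in_bins(sort(centers), bins)
    anchors <- interval_center(bins$start, bins$end)
    X <- .features_at(tracks, rep(ch, nrow(bins)), anchors, mode, flank,
                      sentinel_lengths = lens)
    flags <- attr(X, "flags")
    df <- data.frame(chrom = ch, start = bins$start, end = bins$end,
                     label = as.integer(nhit > 0L), stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(X))
    if (!is.null(pwm)) {
      sc <- scan_bins(pwm, genome[[ch]], chrom = ch, bin_size = bin_size)
      df$pwm_score <- sc$pwm_score
      flags <- ifelse(sc$unscorable,
                      ifelse(nzchar(flags),
                             paste(flags, "unscorable", sep = ";"),
                             "unscorable"),
                      flags)
    }
    df$flags <- flags
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# number of site centers falling in each half-open bin
.count_sites_in_bins <- function(centers_sorted, bins) {
  findInterval(bins$end - 0.5, centers_sorted) -
    findInterval(bins$start - 0.5, centers_sorted)
}

#' Combine classifier probability and PWM score into one region score
#'
#' The default fuses the two `[0,1]` factors multiplicatively
#' (`lrc_proba * pwm_score`), preserving ranking dominance in each factor.
#' `method = "loglinear"` offers a weighted geometric mean
#' `exp(w log p + (1-w) log s)` as an alternative fusion.
#'
#' @param lrc_proba Classifier probabilities in `[0, 1]`.
#' @param pwm_score Scaled PWM scores in `[0, 1]`.
#' @param method `"product"` (default) or `"loglinear"`.
#' @param weight Weight on the classifier factor for `"loglinear"`
#'   (default 0.5).
#' @return Combined scores in `[0, 1]`.
#' @export
combine_scores <- function(lrc_proba, pwm_score,
                           method = c("product", "loglinear"),
                           weight = 0.5) {
  method <- match.arg(method)
  if (any(lrc_proba < 0 | lrc_proba > 1, na.rm = TRUE))
    stop("'lrc_proba' must lie in [0, 1]")
  if (any(pwm_score < 0 | pwm_score > 1, na.rm = TRUE))
    stop("'pwm_score' must lie in [0, 1]")
  if (method == "product") return(lrc_proba * pwm_score)
  if (weight < 0 || weight > 1) stop("'weight' must lie in [0, 1]")
  out <- exp(weight * log(lrc_proba) + (1 - weight) * log(pwm_score))
  out[lrc_proba == 0 | pwm_score == 0] <- 0
  out
}

#' Score test intervals with a classifier trained on another factor
#'
#' The epigenetic signal around binding regions is largely shared between
#' transcription factors, so a classifier trained on one factor's sites can
#' score intervals for another factor once made specific through that
#' factor's PWM: each interval receives
#' `combine_scores(lrc_proba, pwm_score)`.
#'
#' @param model A fitted [lrc()] model (trained on factor A).
#' @param test_set data.frame from [build_test_set()] whose `pwm_score`
#'   column was computed with factor B's PWM.
#' @param combine Fusion method, see [combine_scores()].
#' @param weight Log-linear weight, see [combine_scores()].
#' @return `test_set` with `lrc_proba` and `combined_score` columns added.
#' @export
transfer_predict <- function(model, test_set,
                             combine = c("product", "loglinear"),
                             weight = 0.5) {
  combine <- match.arg(combine)
  if (!"pwm_score" %in% names(test_set))
    stop("'test_set' lacks a pwm_score column (build it with a PWM)")
  test_set$lrc_proba <- predict(model, test_set)
  test_set$combined_score <- combine_scores(test_set$lrc_proba,
                                            test_set$pwm_score,
                                            method = combine,
                                            weight = weight)
  test_set
}

#' Run the full prediction pipeline from a configuration
#'
#' Generates (or reads) the dataset, builds the PWM from training-chromosome
#' site sequences, assembles the training set (site-centered positives, 2:1
#' sampled negatives), fits the classifier, bins and scores the test
#' chromosomes, fuses classifier and PWM scores, and evaluates ROC/AUC.
#' All outputs are written under `out_dir` and the whole run is a pure
#' function of (inputs, seed, config): two runs with the same configuration
#' produce byte-identical files.
#'
#' @param config A configuration list or path to a YAML file; see
#'   [read_run_config()] for keys and defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted `model`, `pwm`, `train` set,
#'   `scores` data.frame, `roc` (list with `pwm`, `lrc`, `combined`
#'   roc_results) and `paths` of the written files.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(cfg$data_dir)) {
    spec <- do.call(synthetic_spec,
                    c(cfg$simulate %||% list(),
                      if (is.null(cfg$simulate$seed)) list(seed = cfg$seed)))
    data_dir <- file.path(out_dir, "data")
    generate_dataset(spec, data_dir)
  } else {
    data_dir <- cfg$data_dir
  }

  genome <- read_genome_fasta(file.path(data_dir, "genome.fa"))
  sites <- read_gff_sites(file.path(data_dir, "sites.gff"), cfg$tf_name)
  track_files <- sort(list.files(file.path(data_dir, "tracks"),
                                 full.names = TRUE, pattern = "\\.tsv$"))
  tracks <- lapply(track_files, function(f)
    read_nucleosome_track(f, sub("\\.tsv$", "", basename(f))))

  train_chrom <- cfg$train_chrom
  test_chroms <- setdiff(names(genome), train_chrom)
  if (!train_chrom %in% names(genome))
    stop("train_chrom not in genome: ", train_chrom)
  if (length(test_chroms) == 0L)
    stop("no test chromosomes left after holding out ", train_chrom)

  train_sites <- sites[sites$chrom == train_chrom, , drop = FALSE]
  attr(train_sites, "tf_name") <- attr(sites, "tf_name")
  class(train_sites) <- class(sites)
  if (nrow(train_sites) == 0L)
    stop("no binding sites on training chromosome ", train_chrom)

  pwm <- build_pwm(extract_site_sequences(train_sites, genome),
                   pseudocount_total = cfg$pseudocount)
  train <- build_training_set(train_sites, tracks,
                              genome[train_chrom], mode = cfg$mode,
                              marks = cfg$marks, flank = cfg$flank,
                              negative_ratio = cfg$negative_ratio,
                              seed = cfg$seed)
  model <- lrc(train, lambda = cfg$lambda)
  test <- build_test_set(genome, sites, tracks, pwm = pwm, mode = cfg$mode,
                         marks = cfg$marks, test_chroms = test_chroms,
                         bin_size = cfg$bin_size, flank = cfg$flank)
  test <- transfer_predict(model, test, combine = cfg$combine,
                           weight = cfg$combine_weight)

  roc <- list(pwm = averaged_roc(test$pwm_score, test$label, test$chrom),
              lrc = averaged_roc(test$lrc_proba, test$label, test$chrom),
              combined = averaged_roc(test$combined_score, test$label,
                                      test$chrom))

  paths <- list(scores = file.path(out_dir, "scores.tsv"),
                train_features = file.path(out_dir, "train_features.tsv"),
                model = file.path(out_dir, "model.json"),
                pwm = file.path(out_dir, "pwm.json"),
                roc = file.path(out_dir, "roc_combined.tsv"),
                log = file.path(out_dir, "run_log.txt"))
  write_scores(test, paths$scores)
  write_features(train, paths$train_features)
  write_lrc(model, paths$model)
  write_pwm(pwm, paths$pwm)
  write_roc(roc$combined, paths$roc)
  .write_run_log(paths$log, cfg, data_dir, roc)

  invisible(list(config = cfg, model = model, pwm = pwm, train = train,
                 scores = test, roc = roc, paths = paths))
}

.write_run_log <- function(path, cfg, data_dir, roc) {
  inputs <- sort(list.files(data_dir, recursive = TRUE, full.names = TRUE))
  sums <- tools::md5sum(inputs)
  lines <- c(
    sprintf("epimotif %s", as.character(utils::packageVersion("epimotif"))),
    sprintf("seed: %d", cfg$seed),
    "config:",
    paste0("  ", strsplit(yaml::as.yaml(
      cfg[!vapply(cfg, is.null, logical(1))]), "\n")[[1]]),
    "input checksums:",
    sprintf("  %s  %s", unname(sums),
            file.path(basename(dirname(inputs)), basename(inputs))),
    sprintf("AUC pwm: %.6f", roc$pwm$auc),
    sprintf("AUC lrc: %.6f", roc$lrc$auc),
    sprintf("AUC combined: %.6f", roc$combined$auc))
  writeLines(lines, path)
  invisible(path)
}
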