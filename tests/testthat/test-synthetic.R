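test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(center_depletion = 200, peak_offset = 150),
               "center_depletion")
  expect_error(synthetic_spec(gc_content = 1.2))
  expect_error(synthetic_spec(bg_rate_active = -1))
  expect_error(synthetic_spec(motif_consensus = "ACGX"))
  expect_error(synthetic_spec(gap_runs = list(c(-5, 10))))
  expect_error(synthetic_spec(
    marks = data.frame(mark = "m", class = "odd")))
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(small_spec(seed = 33), d1)
  generate_dataset(small_spec(seed = 33), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  d3 <- withr::local_tempdir()
  generate_dataset(small_spec(seed = 34), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "genome.fa"))),
    unname(tools::md5sum(file.path(d3, "genome.fa")))))
})

test_that("with no background every active nucleosome hugs a site", {
  spec <- small_spec(seed = 35, bg_rate_active = 0,
                     marks = data.frame(mark = "H3K4me3", class = "active"))
  d <- generate_dataset(spec, withr::local_tempdir())
  lim <- spec$peak_offset + 4 * spec$peak_sd
  for (ch in names(d$tracks$H3K4me3$centers)) {
    cen <- d$tracks$H3K4me3$centers[[ch]]
    sc <- sort(d$sites$center[d$sites$chrom == ch])
    dist <- nearest_nucleosome_distance(
      nucleosome_track("sites", rep(ch, length(sc)), sc), ch, cen)
    expect_true(all(dist <= lim))
  }
})

test_that("repressive centers are uniform over the chromosome (KS test)", {
  spec <- synthetic_spec(n_chromosomes = 1L, chrom_length = 1e6,
                         n_sites = 50L, seed = 36,
                         bg_rate_repressive = 1,
                         marks = data.frame(mark = "H3K9me3",
                                            class = "repressive"))
  d <- generate_dataset(spec, withr::local_tempdir())
  cen <- d$tracks$H3K9me3$centers$chr1
  expect_gt(length(cen), 800)
  p <- suppressWarnings(
    ks.test(cen / spec$chrom_length, "punif")$p.value)
  expect_gt(p, 0.01)
})

test_that("emitted files parse through the package's own readers", {
  d <- generate_dataset(small_spec(seed = 37), withr::local_tempdir())
  g <- read_genome_fasta(d$paths$genome)
  expect_identical(g, d$genome)
  s <- read_gff_sites(d$paths$sites, "SynTF")
  expect_equal(s$start, d$sites$start)
  expect_equal(s$center, d$sites$center)
  expect_equal(s$strand, d$sites$strand)
  for (i in seq_along(d$paths$tracks)) {
    mark <- sub("\\.tsv$", "", basename(d$paths$tracks[i]))
    tr <- read_nucleosome_track(d$paths$tracks[i], mark)
    expect_identical(tr$centers, d$tracks[[mark]]$centers, label = mark)
  }
  # planted instances really carry the motif: site sequences match the
  # consensus at ~1 - mutation_rate per position
  seqs <- extract_site_sequences(s, g)
  cons <- chars_of(d$spec$motif_consensus)
  agree <- vapply(seqs, function(x) mean(chars_of(x) == cons), numeric(1))
  expect_gt(mean(agree), 1 - d$spec$mutation_rate - 0.05)
  expect_lt(mean(agree), 1 - d$spec$mutation_rate + 0.05)
})

test_that("planted sites avoid gaps and chromosome edges", {
  d <- generate_dataset(small_spec(seed = 38), withr::local_tempdir())
  L <- nchar(d$spec$motif_consensus)
  for (ch in unique(d$sites$chrom)) {
    seq <- d$genome[[ch]]
    sdf <- d$sites[d$sites$chrom == ch, ]
    expect_true(all(sdf$start >= L))
    expect_true(all(sdf$end <= nchar(seq) - L))
    for (k in seq_len(nrow(sdf)))
      expect_false(grepl("N", substr(seq, sdf$start[k] + 1, sdf$end[k])))
    # non-overlapping
    expect_true(all(diff(sdf$start) >= L))
  }
})

test_that("enrichment drives feature separation; no enrichment, none", {
  spec_on <- small_spec(seed = 39, n_sites = 60L)
  d <- generate_dataset(spec_on, withr::local_tempdir())
  tr_sites <- d$sites[d$sites$chrom == "chr1", ]
  class(tr_sites) <- class(d$sites)
  attr(tr_sites, "tf_name") <- "SynTF"
  ts <- build_training_set(tr_sites, d$tracks, d$genome["chr1"],
                           mode = "mnn", seed = 1)
  # positives' nearest active nucleosome is stochastically much closer
  med_pos <- median(ts$X[ts$y == 1, "mnn_H3K4me3"])
  med_neg <- median(ts$X[ts$y == 0, "mnn_H3K4me3"])
  expect_lt(med_pos, med_neg / 2)
  fit <- lrc(ts)
  a_on <- auc(predict(fit, ts$X), ts$y)
  expect_gt(a_on, 0.8)  # at this miniature density; higher at scale

  # with enrichment off the same pipeline is at chance level
  spec_off <- small_spec(seed = 39, n_sites = 60L, nuc_per_site = 0L,
                         bg_rate_active = 1)
  d0 <- generate_dataset(spec_off, withr::local_tempdir())
  tr0 <- d0$sites[d0$sites$chrom == "chr1", ]
  class(tr0) <- class(d0$sites)
  attr(tr0, "tf_name") <- "SynTF"
  ts0 <- build_training_set(tr0, d0$tracks, d0$genome["chr1"],
                            mode = "mnn", seed = 1)
  fit0 <- lrc(ts0)
  a_off <- auc(predict(fit0, ts0$X), ts0$y)
  expect_lt(a_off, a_on - 0.2)
})
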