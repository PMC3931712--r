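track1 <- nucleosome_track("H3K4me3", rep("chr1", 2), c(4000, 5300))

test_that("nearest-nucleosome distance picks the closer neighbor", {
  tr <- nucleosome_track("H3K4me3", "chr1", 5000)
  expect_equal(nearest_nucleosome_distance(tr, "chr1", 5000), 0)
  expect_equal(nearest_nucleosome_distance(track1, "chr1", 5000), 300)
  expect_error(nearest_nucleosome_distance(track1, "chr2", 5000),
               "chr2")
})

test_that("binary-search nearest distance equals the linear-scan oracle", {
  set.seed(10)
  for (k in 1:20) {
    centers <- sort(sample.int(1e5, sample(1:200, 1)))
    tr <- nucleosome_track("m", rep("c", length(centers)), centers)
    pos <- sample.int(1.2e5, 50) - 1e4  # anchors beyond both track ends too
    pos <- pmax(pos, 0)
    expect_equal(nearest_nucleosome_distance(tr, "c", pos),
                 brute_nearest(centers, pos))
  }
})

test_that("occupancy counts centers in a closed window", {
  tr <- nucleosome_track("m", rep("chr1", 3), c(4000, 5000, 6100))
  expect_equal(occupancy_count(tr, "chr1", 5000, 1000), 2L)
  expect_equal(occupancy_count(tr, "chr2", 5000, 1000), 0L)  # empty -> 0
  tr2 <- nucleosome_track("m", rep("chr1", 2), c(4000, 6000))
  expect_equal(occupancy_count(tr2, "chr1", 5000, 1000), 2L)  # edges count
  expect_error(occupancy_count(tr, "chr1", 5000, 0))
})

test_that("occupancy is monotone in the flank and matches the oracle", {
  set.seed(11)
  centers <- sort(sample.int(5e4, 300))
  tr <- nucleosome_track("m", rep("c", 300), centers)
  pos <- sample.int(5e4, 30)
  prev <- rep(-1, 30)
  for (flank in c(100, 500, 1000, 5000)) {
    cnt <- occupancy_count(tr, "c", pos, flank)
    expect_equal(cnt, as.integer(brute_occupancy(centers, pos, flank)))
    expect_true(all(cnt >= prev))
    prev <- cnt
  }
})

test_that("per-mark vectors keep the given track order and names", {
  tracks <- list(track1, nucleosome_track("H2A.Z", "chr1", 4900))
  v <- mnn_vector(tracks, "chr1", 5000)
  expect_named(v, c("mnn_H3K4me3", "mnn_H2A.Z"))
  expect_equal(unname(v), c(300, 100))
  w <- mno_vector(tracks, "chr1", 5000, flank = 1000)
  expect_named(w, c("mno_H3K4me3", "mno_H2A.Z"))
  expect_equal(unname(w), c(2, 1))
})

test_that("profiles place unit footprints and normalize by site count", {
  sites1 <- binding_sites("chr1", 4990, 5010)  # center 5000
  tr <- nucleosome_track("m", "chr1", 5000)
  pr <- position_profile(tr, sites1)
  expect_equal(nrow(pr), 2031L)
  expect_equal(range(pr$offset), c(-1015L, 1015L))
  expect_equal(pr$ratio[abs(pr$offset) <= 15], rep(1, 31))
  expect_equal(sum(pr$ratio), 31)

  sites2 <- binding_sites(c("chr1", "chr1"), c(4990, 8990), c(5010, 9010))
  pr2 <- position_profile(tr, sites2)
  expect_equal(pr2$ratio[abs(pr2$offset) <= 15], rep(0.5, 31))
  expect_error(position_profile(tr, sites1[0, ]))
})

test_that("profiles equal the brute-force double loop", {
  set.seed(12)
  for (k in 1:5) {
    centers <- sort(sample.int(4000, 60))
    sc <- sort(sample(500:3500, 8))
    tr <- nucleosome_track("m", rep("c", 60), centers)
    sites <- binding_sites(rep("c", 8), sc - 5, sc + 5)
    hw <- 300; fp <- 15
    pr <- position_profile(tr, sites, half_window = hw, footprint = fp)
    expect_equal(pr$ratio, brute_profile(centers, sites$center, hw, fp))
  }
})

test_that("features are invariant under joint translation", {
  set.seed(13)
  centers <- sort(sample.int(5e4, 100))
  sc <- sort(sample(2000:45000, 10))
  shift <- 12345L
  tr <- nucleosome_track("m", rep("c", 100), centers)
  trs <- nucleosome_track("m", rep("c", 100), centers + shift)
  expect_equal(nearest_nucleosome_distance(tr, "c", sc),
               nearest_nucleosome_distance(trs, "c", sc + shift))
  expect_equal(occupancy_count(tr, "c", sc, 800),
               occupancy_count(trs, "c", sc + shift, 800))
  s1 <- binding_sites(rep("c", 10), sc - 3, sc + 3)
  s2 <- binding_sites(rep("c", 10), sc - 3 + shift, sc + 3 + shift)
  expect_equal(position_profile(tr, s1)$ratio,
               position_profile(trs, s2)$ratio)
})

test_that("total profile mass equals the enumerated footprint overlap", {
  set.seed(14)
  centers <- sort(sample.int(3000, 40))
  sc <- sort(sample(400:2600, 5))
  tr <- nucleosome_track("m", rep("c", 40), centers)
  sites <- binding_sites(rep("c", 5), sc - 2, sc + 2)
  hw <- 200; fp <- 15; W <- hw + fp
  pr <- position_profile(tr, sites, half_window = hw, footprint = fp)
  total <- 0
  for (s in sites$center) for (cc in centers) {
    d <- cc - s
    if (abs(d) <= W)
      total <- total + (min(d + fp, W) - max(d - fp, -W) + 1)
  }
  expect_equal(sum(pr$ratio) * nrow(sites), total)
})
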