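test_that("thresholding emits one event per suprathreshold (neuron, step)", {
  nrows <- 10
  rates <- matrix(0, 100, 20)
  expect_equal(nrow(threshold_to_pseudospikes(fake_trace(rates, nrows), 0.4)), 0)

  rates[35, 6:15] <- 1  # neuron 35 = (x=4, y=3)
  cl <- threshold_to_pseudospikes(fake_trace(rates, nrows), 0.4)
  expect_equal(nrow(cl), 10)
  expect_true(all(cl$x == 4 & cl$y == 3 & cl$neuron == 35))
  expect_equal(cl$t, 6:15)

  set.seed(12)
  rates <- matrix(runif(100 * 20), 100, 20)
  cl <- threshold_to_pseudospikes(fake_trace(rates, nrows), 0.4)
  expect_equal(nrow(cl), sum(rates >= 0.4))  # inclusive threshold
})

test_that("toroidal clustering recovers planted clusters incl. the seam", {
  g <- build_grid(40)
  par <- detection_params(eps = 4, min_samples = 20)

  cloud <- generate_fixtures("cloud", list(nrows = 40), seed = 5)
  seqs <- cluster_toroidal(cloud, par, g)
  expect_length(seqs, 3)
  # partition matches the planted labels and the brute-force toroidal oracle
  planted <- attr(cloud, "planted")
  lab <- integer(nrow(cloud))
  for (s in seqs) lab[as.integer(rownames(s$events))] <- s$id
  expect_true(same_partition_core(lab, planted))  # a few planted outliers may be noise
  oracle <- oracle_toroidal_dbscan(cloud, 4, 20, 40)
  expect_true(same_partition_core(lab, oracle))

  # a dense blob straddling the x-seam is one cluster, not two
  seam <- generate_fixtures("cloud", list(nrows = 40, clusters = list(
    list(center = c(0, 10, 100), n = 120, spread = 2, t_spread = 15))), seed = 6)
  expect_true(any(seam$x > 35) && any(seam$x < 5))
  sseq <- cluster_toroidal(seam, par, g)
  expect_length(sseq, 1)
  seam_oracle <- oracle_toroidal_dbscan(seam, 4, 20, 40)
  expect_equal(length(unique(seam_oracle[seam_oracle > 0])), 1)
  lab_seam <- integer(nrow(seam))
  for (s in sseq) lab_seam[as.integer(rownames(s$events))] <- s$id
  expect_true(same_partition_core(lab_seam, seam_oracle))

  # isolated sparse events are all noise
  iso <- data.frame(x = seq(0, 29, by = 6) %% 40, y = rep(c(5, 25, 35), 10)[1:5],
                    t = seq(0, 4000, length.out = 5))
  iso <- iso[rep(1:5, 6), ]; iso$t <- iso$t + rep(seq(0, 2500, by = 500), each = 5)
  iso$neuron <- as.integer(iso$y * 40 + iso$x + 1)
  attr(iso, "nrows") <- 40; class(iso) <- c("stas_cloud", "data.frame")
  expect_length(cluster_toroidal(iso, detection_params(min_samples = 50), g), 0)
})

test_that("clustering is invariant under toroidal translation", {
  g <- build_grid(40)
  par <- detection_params(eps = 4, min_samples = 20)
  cloud <- generate_fixtures("cloud", list(nrows = 40), seed = 8)
  base <- cluster_toroidal(cloud, par, g)
  set.seed(2)
  for (k in 1:3) {
    sh <- sample(0:39, 2)
    tc <- cloud
    tc$x <- (tc$x + sh[1]) %% 40
    tc$y <- (tc$y + sh[2]) %% 40
    tc$neuron <- as.integer(tc$y * 40 + tc$x + 1)
    tr <- cluster_toroidal(tc, par, g)
    expect_equal(length(tr), length(base))
    expect_setequal(sapply(tr, function(s) nrow(s$events)),
                    sapply(base, function(s) nrow(s$events)))
  }
})

test_that("extent filtering removes stationary blobs, keeps travelers", {
  g <- build_grid(40)
  nrows <- 40
  stat <- fake_sequence(1, cbind(rep(10, 60), rep(10, 60)), 100, nrows)
  trav <- fake_sequence(2, cbind(5:16, rep(20, 12)), 100, nrows)
  kept <- filter_sequences(list(stat, trav), detection_params(min_extent = 8), g)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$events$x[1], 5)

  # extents equal the O(n^2) oracle, including across the seam
  wrap <- fake_sequence(3, cbind(c(36:39, 0:3), rep(7, 8)), 50, nrows)
  expect_equal(wrap$extent, 7)  # toroidal, not 39
  set.seed(4)
  xy <- cbind(sample(0:39, 25, TRUE), sample(0:39, 25, TRUE))
  sq <- fake_sequence(4, xy, 0, nrows)
  expect_equal(sq$extent, oracle_extent(unique(xy), nrows), tolerance = 1e-12)

  # static-bump screening
  expect_true(is_static_bump_run(list(fake_sequence(
    5, cbind(rep(3, 3700), rep(3, 3700)), 1, nrows)), t_sim = 4000))
  expect_false(is_static_bump_run(list(trav), t_sim = 4000))
})

test_that("sequence landscape counts per-neuron participation", {
  g <- build_grid(40)
  s1 <- fake_sequence(1, cbind(5:14, rep(20, 10)), 0, 40)
  s2 <- fake_sequence(2, cbind(10:19, rep(20, 10)), 500, 40)
  land <- sequence_landscape(list(s1, s2), g)
  tally <- integer(1600)
  for (s in list(s1, s2)) tally[s$neurons] <- tally[s$neurons] + 1L
  expect_identical(land$count, tally)
  expect_equal(max(land$count), 2)  # the shared neurons
  expect_equal(sum(land$count), 20)
})

test_that("spot crossings match a brute-force distance filter", {
  g <- build_grid(40)
  s1 <- fake_sequence(1, cbind(5:30, rep(20, 26)), 100, 40)   # passes both
  s2 <- fake_sequence(2, cbind(rep(35, 10), 1:10), 100, 40)   # outside
  spots <- list(detection_spot("a", c(8, 20)), detection_spot("b", c(28, 20)))
  cr <- spot_crossings(list(s1, s2), spots, g)
  expect_equal(nrow(cr), 4)
  expect_true(all(cr$crossed[cr$seq_id == 1]))
  expect_true(all(!cr$crossed[cr$seq_id == 2]))
  # first crossing times ordered along the motion
  ta <- cr$t_first[cr$seq_id == 1 & cr$spot == "a"]
  tb <- cr$t_first[cr$seq_id == 1 & cr$spot == "b"]
  expect_lt(ta, tb)
  # oracle: earliest event within radius 2
  ev <- s1$events
  d <- sapply(seq_len(nrow(ev)), function(i)
    oracle_toroidal_distance(c(ev$x[i], ev$y[i]), c(8, 20), 40))
  expect_equal(ta, min(ev$t[d <= 2]))
})

test_that("network effect summaries use matched seeds and textbook SEM", {
  b <- data.frame(seed = 1:4, count = c(10, 12, 9, 11), duration = c(50, 60, 55, 52))
  expect_equal(network_effect_summary(b, b)$d_count, 0)
  expect_equal(network_effect_summary(b, b)$d_count_sem, 0)

  m <- data.frame(seed = 1:4, count = c(13, 15, 11, 15), duration = c(70, 75, 60, 71))
  eff <- network_effect_summary(b, m)
  dc <- m$count - b$count
  expect_equal(eff$d_count, mean(dc))
  expect_equal(eff$d_count_sem, sd(dc) / sqrt(4))

  set.seed(31)
  b2 <- data.frame(seed = 1:100, count = rpois(100, 20), duration = rnorm(100, 60, 5))
  m2 <- data.frame(seed = 1:100, count = rpois(100, 25), duration = rnorm(100, 70, 5))
  eff2 <- network_effect_summary(b2, m2)
  dd <- m2$duration - b2$duration
  expect_equal(eff2$d_duration_sem, sd(dd) / 10, tolerance = 1e-12)

  expect_error(network_effect_summary(b, transform(m, seed = 5:8)), "matched")
})
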