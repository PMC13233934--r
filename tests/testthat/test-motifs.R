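mk_crossings <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(seq_id = r[[1]], spot = r[[2]], crossed = r[[3]],
               t_first = r[[4]])))
}

test_that("transmission counts ordered crossings", {
  cr <- mk_crossings(
    list("s1", "pre", TRUE, 100), list("s1", "post", TRUE, 150),
    list("s2", "pre", TRUE, 200), list("s2", "post", FALSE, NA),
    list("s3", "pre", FALSE, NA), list("s3", "post", TRUE, 300))
  tr <- transmission(cr, "pre", "post")
  expect_equal(tr$n_pre, 2); expect_equal(tr$n_post, 2)
  expect_equal(tr$n_ordered_both, 1)
  expect_equal(tr$p_post_given_pre, 0.5)
  expect_equal(tr$p_pre_given_post, 0.5)

  # all sequences cross both in order -> both probabilities 1
  cr2 <- mk_crossings(list("a", "pre", TRUE, 1), list("a", "post", TRUE, 2),
                      list("b", "pre", TRUE, 5), list("b", "post", TRUE, 9))
  tr2 <- transmission(cr2, "pre", "post")
  expect_equal(tr2$p_post_given_pre, 1)
  expect_equal(tr2$p_pre_given_post, 1)

  # undefined ratios are NA, never 0
  cr3 <- mk_crossings(list("a", "pre", FALSE, NA), list("a", "post", TRUE, 4))
  expect_true(is.na(transmission(cr3, "pre", "post")$p_post_given_pre))

  # randomized tables match the enumeration oracle
  set.seed(55)
  for (k in 1:10) {
    n <- 30
    cr4 <- do.call(rbind, lapply(seq_len(n), function(i) {
      ca <- runif(1) < 0.6; cb <- runif(1) < 0.5
      rbind(data.frame(seq_id = paste0("q", i), spot = "pre", crossed = ca,
                       t_first = if (ca) runif(1, 0, 1000) else NA),
            data.frame(seq_id = paste0("q", i), spot = "post", crossed = cb,
                       t_first = if (cb) runif(1, 0, 1000) else NA))
    }))
    got <- transmission(cr4, "pre", "post")
    want <- oracle_transmission(cr4, "pre", "post")
    expect_equal(got$n_pre, want$n_pre)
    expect_equal(got$n_post, want$n_post)
    expect_equal(got$n_both, want$n_both)
    expect_equal(got$n_ordered_both, want$n_ordered)
  }
})

test_that("pooled and per-run transmission estimators agree on balanced runs", {
  set.seed(8)
  runs <- lapply(1:5, function(r) {
    do.call(rbind, lapply(1:40, function(i) {
      ca <- runif(1) < 0.5; cb <- ca && runif(1) < 0.6
      rbind(data.frame(seq_id = i, spot = "pre", crossed = ca,
                       t_first = if (ca) 10 else NA),
            data.frame(seq_id = i, spot = "post", crossed = cb,
                       t_first = if (cb) 20 else NA))
    }))
  })
  pooled <- transmission(pool_crossings(runs), "pre", "post")
  per <- transmission_by_run(runs, "pre", "post")
  expect_equal(nrow(per$per_run), 5)
  # equal per-run sizes: pooled ratio ~ mean of per-run ratios
  expect_equal(pooled$p_post_given_pre, per$mean_p_post_given_pre,
               tolerance = 0.12)
})

test_that("motif report flags effect directions", {
  b <- transmission(mk_crossings(
    list("a", "pre", TRUE, 1), list("a", "post", TRUE, 2),
    list("b", "pre", TRUE, 1), list("b", "post", FALSE, NA)), "pre", "post")
  same <- motif_report(b, b)
  expect_equal(same$d_p_post_given_pre, 0)
  expect_equal(same$direction_p_post_given_pre, "none")

  p <- transmission(mk_crossings(
    list("a", "pre", TRUE, 1), list("a", "post", TRUE, 2),
    list("b", "pre", TRUE, 1), list("b", "post", TRUE, 3),
    list("c", "pre", TRUE, 1), list("c", "post", TRUE, 2)), "pre", "post")
  rep_up <- motif_report(b, p)
  expect_equal(rep_up$direction_p_post_given_pre, "increase")
  expect_equal(rep_up$direction_n_pre, "increase")
})

test_that("branch episodes classify single, competition and cooperation", {
  g <- build_grid(40)
  spots <- list(M = detection_spot("M", c(26, 20)),
                B1 = detection_spot("B1", c(12, 25)),
                B2 = detection_spot("B2", c(12, 15)))
  win <- branch_window(200, spots)

  # one sequence down B2 then M only -> single
  s1 <- fake_sequence(1, cbind(c(10:26), round(seq(15, 20, length.out = 17))),
                      100, 40)
  cr1 <- spot_crossings(list(s1), unname(spots), g)
  ep1 <- branch_episodes(list(s1), win, cr1, g)
  expect_length(ep1, 1)
  expect_equal(ep1[[1]]$classification, "single")

  # two sequences, one per branch, 50 ms apart, only one reaches M
  s2 <- fake_sequence(2, cbind(10:26, round(seq(25, 20, length.out = 17))), 100, 40)
  s3 <- fake_sequence(3, cbind(10:16, round(seq(15, 13, length.out = 7))), 150, 40)
  cr23 <- spot_crossings(list(s2, s3), unname(spots), g)
  ep2 <- branch_episodes(list(s2, s3), win, cr23, g)
  expect_length(ep2, 1)
  expect_equal(ep2[[1]]$classification, "competition")
  expect_true(!is.na(ep2[[1]]$max_competition_time))

  # one merged cloud touching B1, B2 and M -> cooperation; the two arms
  # become density-connected at the planted junction time
  arm1 <- cbind(10:25, round(seq(25, 20, length.out = 16)))
  arm2 <- cbind(10:25, round(seq(15, 20, length.out = 16)))
  path <- rbind(arm1, arm2, cbind(26:28, rep(20, 3)))
  tt <- c(100 + 0:15, 100 + 0:15, 116:118)
  ev <- data.frame(x = path[, 1], y = path[, 2], t = tt,
                   neuron = as.integer(path[, 2] * 40 + path[, 1] + 1))
  s4 <- structure(list(id = 4, events = ev, neurons = sort(unique(ev$neuron)),
                       t_start = 100, t_end = 118, duration = 18,
                       extent = oracle_extent(as.matrix(path), 40)),
                  class = "stas_sequence")
  cr4 <- spot_crossings(list(s4), unname(spots), g)
  ep3 <- branch_episodes(list(s4), win, cr4, g, eps = 4)
  expect_equal(ep3[[1]]$classification, "cooperation")
  # arms are 10 apart at t=100 and converge linearly; they come within 4
  # grid points around t = 109
  expect_true(abs(ep3[[1]]$merge_time - 109) <= 2)
  expect_true(all(c("M", "B1", "B2") %in% names(ep3[[1]]$counts)))
})

test_that("episodes outside the window are split apart", {
  g <- build_grid(40)
  spots <- list(M = detection_spot("M", c(26, 20)),
                B1 = detection_spot("B1", c(12, 25)),
                B2 = detection_spot("B2", c(12, 15)))
  win <- branch_window(200, spots)
  s2 <- fake_sequence(2, cbind(10:26, round(seq(25, 20, length.out = 17))), 100, 40)
  s3 <- fake_sequence(3, cbind(10:16, round(seq(15, 13, length.out = 7))), 900, 40)
  cr <- spot_crossings(list(s2, s3), unname(spots), g)
  eps <- branch_episodes(list(s2, s3), win, cr, g)
  expect_length(eps, 2)
  expect_setequal(sapply(eps, `[[`, "classification"), c("single", "single"))
})
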