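test_that("patch selection samples the disk uniformly and reproducibly", {
  g <- build_grid(100)
  p <- make_patch(c(50, 50), 6, 40, 0.10, g, seed = 1)
  expect_length(p$selected, 40)
  expect_equal(p$disk_size, 113)
  disk <- neurons_in_disk(c(50, 50), 6, g)
  expect_true(all(p$selected %in% disk))
  expect_identical(p$selected,
                   make_patch(c(50, 50), 6, 40, 0.10, g, seed = 1)$selected)

  # n_rec = disk size selects the whole disk
  pall <- make_patch(c(50, 50), 6, 113, 0.10, g, seed = 2)
  expect_setequal(pall$selected, disk)

  # Monte-Carlo: every disk neuron selected with frequency ~ 40/113
  counts <- integer(113)
  for (s in 1:1000) {
    sel <- make_patch(c(50, 50), 6, 40, 0.10, g, seed = 1000 + s)$selected
    counts <- counts + disk %in% sel
  }
  p_hat <- counts / 1000
  tol <- 4 * sqrt((40 / 113) * (1 - 40 / 113) / 1000)
  expect_true(all(abs(p_hat - 40 / 113) < tol))

  expect_error(make_patch(c(50, 50), 2, 40, 0.10, g, seed = 1), "disk")
  expect_error(make_patch(c(50, 50), 6, 40, -1.2, g, seed = 1), "p")
})

test_that("apply_patch scales only the scoped incoming weights", {
  g <- build_grid(16)
  f <- sample_direction_field(g, 4, seed = 3)
  conn <- build_connectome(g, f, kernel_params(n_out_exc = 120, n_out_inh = 30),
                           J = 0.5, g = 8, seed = 5)
  patch <- make_patch(c(8, 8), 4, 10, 0.10, g, seed = 7)

  p0 <- patch; p0$p <- 0
  m0 <- apply_patch(conn, p0)
  expect_equal(m0$weights, conn$weights)

  mp <- apply_patch(conn, patch)
  ne <- conn$n_exc
  W0 <- as.matrix(conn$weights); W1 <- as.matrix(mp$weights)
  sel <- patch$selected
  expect_equal(W1[sel, 1:ne], W0[sel, 1:ne] * 1.1)
  expect_equal(W1[-sel, ], W0[-sel, ])                    # other rows untouched
  expect_equal(W1[sel, (ne + 1):ncol(W1)], W0[sel, (ne + 1):ncol(W0)])  # scope ee
  expect_equal(as.matrix(conn$weights), W0)               # original unmodified

  # difference supported only on selected rows x excitatory columns
  dif <- W1 - W0
  expect_true(all(dif[-sel, ] == 0))
  expect_true(all(dif[, (ne + 1):ncol(dif)] == 0))

  # algebraic inverse: -10% then +1/9 recovers the original weights
  pdn <- patch; pdn$p <- -0.10
  pup <- patch; pup$p <- 1 / 9
  back <- apply_patch(apply_patch(conn, pdn), pup)
  expect_equal(as.matrix(back$weights), W0, tolerance = 1e-12)

  # "all" scope also scales incoming inhibition
  pall2 <- patch; pall2$scope <- "all"
  ma <- apply_patch(conn, pall2)
  Wa <- as.matrix(ma$weights)
  expect_equal(Wa[sel, ], W0[sel, ] * 1.1)
})

test_that("non-spatial control samples the whole population", {
  g <- build_grid(16)
  f <- sample_direction_field(g, 4, seed = 3)
  conn <- build_connectome(g, f, kernel_params(n_out_exc = 120, n_out_inh = 30),
                           seed = 5)
  m <- apply_nonspatial_control(conn, n_rec = 40, p = 0.10, seed = 3)
  sel <- attr(m, "control_selected")
  expect_length(sel, 40)
  expect_identical(sel, attr(apply_nonspatial_control(conn, 40, 0.10, seed = 3),
                             "control_selected"))

  # scattered selection: mean pairwise distance well above a patch diameter
  pos <- g$exc_positions[sel, ]
  dd <- outer(seq_along(sel), seq_along(sel), Vectorize(function(i, j)
    toroidal_distance(pos[i, ], pos[j, ], 16)))
  patch_sel <- make_patch(c(8, 8), 4, 40, 0.10, g, seed = 3)$selected
  ppos <- g$exc_positions[patch_sel, ]
  pd <- outer(seq_along(patch_sel), seq_along(patch_sel), Vectorize(function(i, j)
    toroidal_distance(ppos[i, ], ppos[j, ], 16)))
  expect_gt(mean(dd[upper.tri(dd)]), mean(pd[upper.tri(pd)]))

  expect_error(apply_nonspatial_control(conn, n_rec = 1e5), "exceeds")
})
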