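# Small networks with reduced out-degrees keep these tests fast; the
# full-scale out-degree conservation at reference settings is covered in
# test-acceptance.R.

small_kernel <- function(shift = 1)
  kernel_params(shift = shift, n_out_exc = 120, n_out_inh = 30)

test_that("out-degrees are conserved exactly and weights follow k*J / -k*g*J", {
  g <- build_grid(16)
  f <- sample_direction_field(g, 4, seed = 3)
  conn <- build_connectome(g, f, small_kernel(), J = 0.5, g = 8, seed = 5)

  od <- out_degrees(conn)
  expect_true(all(od$onto_exc == 120))
  expect_true(all(od$onto_inh == 30))

  K <- as.matrix(conn$multiplicity)
  W <- as.matrix(conn$weights)
  ne <- conn$n_exc
  expect_true(all(K == round(K) & K >= 0))
  expect_equal(W[, 1:ne], K[, 1:ne] * 0.5)
  expect_equal(W[, (ne + 1):ncol(W)], -8 * 0.5 * K[, (ne + 1):ncol(K)])
  expect_true(all(diag(K) == 0))
})

test_that("connectome construction is deterministic per seed", {
  g <- build_grid(16)
  f <- sample_direction_field(g, 4, seed = 3)
  c1 <- build_connectome(g, f, small_kernel(), seed = 9)
  c2 <- build_connectome(g, f, small_kernel(), seed = 9)
  c3 <- build_connectome(g, f, small_kernel(), seed = 10)
  expect_identical(c1$multiplicity, c2$multiplicity)
  expect_false(identical(c1$multiplicity, c3$multiplicity))
})

test_that("kernel displacement follows shift along phi for E->E draws", {
  g <- build_grid(16)
  unif <- structure(list(phi = rep(0, 256), has_direction = rep(TRUE, 256),
                         noise_cells = NA, seed = NA), class = "stas_field")
  # large n_out for a tight Monte-Carlo bound on one sender's mean target
  k1 <- kernel_params(shift = 1, n_out_exc = 3750, n_out_inh = 30)
  conn <- build_connectome(g, unif, k1, seed = 4)
  pre <- 1 + 8 * 16 + 8  # neuron at (8, 8)
  K <- conn$multiplicity[1:256, pre]
  tgt <- which(K > 0)
  disp <- toroidal_delta(matrix(c(8, 8), length(tgt), 2, byrow = TRUE),
                         g$exc_positions[tgt, ], 16)
  mx <- sum(disp[, 1] * K[tgt]) / sum(K[tgt])
  my <- sum(disp[, 2] * K[tgt]) / sum(K[tgt])
  tol <- 3 * 2.5 / sqrt(3750)
  expect_lt(abs(mx - 1), tol + 0.15)  # snapping adds sub-lattice bias
  expect_lt(abs(my), tol + 0.15)

  k0 <- kernel_params(shift = 0, n_out_exc = 3750, n_out_inh = 30)
  conn0 <- build_connectome(g, unif, k0, seed = 4)
  K0 <- conn0$multiplicity[1:256, pre]
  tgt0 <- which(K0 > 0)
  disp0 <- toroidal_delta(matrix(c(8, 8), length(tgt0), 2, byrow = TRUE),
                          g$exc_positions[tgt0, ], 16)
  expect_lt(abs(sum(disp0[, 1] * K0[tgt0]) / sum(K0[tgt0])), tol + 0.15)

  expect_error(kernel_params(sigma_exc = 5, sigma_inh = 4), "Mexican")
})

test_that("in-degree landscape sums incoming E->E weight mass", {
  g <- build_grid(16)
  f <- sample_direction_field(g, 4, seed = 3)
  conn <- build_connectome(g, f, small_kernel(), J = 0.5, g = 8, seed = 5)
  ind <- in_degree_landscape(conn)
  # oracle: dense double sum over the E->E block
  W <- as.matrix(conn$weights)[1:256, 1:256]
  expect_equal(ind, rowSums(W))
  # conservation: total mass = n_exc senders * n_out_exc * J
  expect_equal(sum(ind), 256 * 120 * 0.5)
  expect_true(all(ind >= 0))
})

test_that("anisotropy with a smooth field raises in-degree heterogeneity", {
  net <- noise_net40()
  defs <- net$defs
  v0 <- v1 <- numeric(0)
  for (s in 1:3) {
    k0 <- kernel_params(shift = 0, n_out_exc = defs$kernel$n_out_exc,
                        n_out_inh = defs$kernel$n_out_inh)
    v0 <- c(v0, var(in_degree_landscape(
      build_connectome(net$geometry, net$field, k0, defs$J, defs$g, seed = 50 + s))))
    v1 <- c(v1, var(in_degree_landscape(
      build_connectome(net$geometry, net$field, defs$kernel, defs$J, defs$g,
                       seed = 50 + s))))
  }
  expect_gt(mean(v1), 2 * mean(v0))

  # spatial smoothness: neighboring in-degrees positively correlated
  ind <- matrix(in_degree_landscape(net$connectome), 40, 40)
  expect_gt(cor(as.vector(ind), as.vector(ind[c(2:40, 1), ])), 0.5)
})

test_that("domain classification uses five equal-width bins with clipping", {
  d <- classify_domains(0:10)
  expect_equal(d$bin_edges, seq(0, 10, by = 2))
  expect_equal(as.character(d$domain_label[c(1, 3, 5, 7, 9, 11)]),
               c("low", "low-mid", "mid", "mid-high", "high", "high"))
  expect_true(all(!is.na(d$domain_label)))

  # clipping: outliers land in the extreme bins, interior edges unaffected
  base <- seq(0, 100, length.out = 201)
  with_out <- c(base, -1e4, 1e4)
  d1 <- classify_domains(base, clip = c(2.5, 97.5))
  d2 <- classify_domains(with_out, clip = c(2.5, 97.5))
  expect_lt(max(abs(d1$bin_edges - d2$bin_edges)), 3)
  expect_equal(as.character(d2$domain_label[202]), "low")
  expect_equal(as.character(d2$domain_label[203]), "high")

  expect_warning(classify_domains(rep(3, 10)), "constant")
})

test_that("edge-list export round-trips multiplicities and weights", {
  g <- build_grid(8)
  f <- sample_direction_field(g, 2, seed = 3)
  conn <- build_connectome(g, f, kernel_params(n_out_exc = 40, n_out_inh = 10),
                           J = 0.275, g = 8, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_edges(conn, path)
  df <- read.delim(path)
  expect_equal(sum(df$k), (64 + 16) * 50)
  expect_equal(df$w, ifelse(df$pre <= 64, df$k * 0.275, -df$k * 8 * 0.275))
})
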