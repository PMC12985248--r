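# D1Q3 lattice-Boltzmann physics encoder.

test_that("lifting applies softplus per channel and stays positive", {
  # zero weights: softplus(0) = log 2 everywhere
  F0 <- lbm_lift(numeric(8), W = c(0, 0, 0), b = c(0, 0, 0))
  expect_equal(F0, matrix(log(2), 8, 3))
  # unit weight, c = 2: softplus(2) = log(1 + e^2)
  F2 <- lbm_lift(rep(2, 4), W = c(1, 1, 1), b = c(0, 0, 0))
  expect_equal(F2[1, 1], log(1 + exp(2)), tolerance = 1e-12)
  # positivity for arbitrary finite inputs
  set.seed(1)
  F3 <- lbm_lift(stats::rnorm(64, sd = 5), W = stats::rnorm(3),
                 b = stats::rnorm(3))
  expect_gt(min(F3), 0)
})

test_that("moment projection zeroes per-site mass and momentum exactly", {
  cfg <- lbm_config()
  e <- cfg$velocities
  set.seed(2)
  worst_mass <- worst_mom <- 0
  for (i in 1:1000) {
    Ct <- matrix(stats::rnorm(3 * 3, sd = 10), 3, 3)
    C <- lbm_project_residual(Ct, cfg)
    worst_mass <- max(worst_mass, max(abs(rowSums(C))))
    worst_mom <- max(worst_mom, max(abs(C %*% e)))
  }
  expect_lt(worst_mass, 1e-6)
  expect_lt(worst_mom, 1e-6)
  # pure mass excess (delta, delta, delta) projects to zero
  Cp <- lbm_project_residual(matrix(0.7, 1, 3), cfg)
  expect_equal(as.numeric(Cp), c(0, 0, 0), tolerance = 1e-12)
})

test_that("the three-over-Q projection variant conserves mass but not momentum", {
  cfg_lit <- lbm_config(projection = "three_over_q")
  set.seed(3)
  Ct <- matrix(stats::rnorm(30), 10, 3)
  C <- lbm_project_residual(Ct, cfg_lit)
  expect_lt(max(abs(rowSums(C))), 1e-12)          # mass still conserved
  # momentum residual equals -Dm (coefficient 3/Q spreads e over sum e^2 = 2)
  dm <- Ct %*% cfg_lit$velocities
  expect_equal(as.numeric(C %*% cfg_lit$velocities), as.numeric(-dm))
})

test_that("zero collision weights give an identity collision", {
  cfg <- lbm_config()
  F <- lbm_lift(stats::rnorm(16), c(1, -1, 0.5), c(0.1, 0, -0.1))
  expect_equal(lbm_collide(F, matrix(0, 3, 3), c(0, 0, 0), cfg), F)
})

test_that("streaming shifts channels circularly and conserves sums", {
  cfg <- lbm_config()
  F <- matrix(0, 8, 3)
  F[3, ] <- c(1, 2, 5)
  S <- lbm_stream(F, cfg)
  expect_equal(S[2, 1], 1)   # e = -1 channel moves back one site
  expect_equal(S[3, 2], 2)   # stationary channel unchanged
  expect_equal(S[4, 3], 5)   # e = +1 channel advects forward
  expect_equal(colSums(S), colSums(F))
  # wrap-around at the boundary
  F2 <- matrix(0, 4, 3); F2[4, 3] <- 1
  expect_equal(lbm_stream(F2, cfg)[1, 3], 1)
})

test_that("moments satisfy the D1Q3 identities", {
  cfg <- lbm_config()
  m1 <- lbm_moments(matrix(2, 1, 3), cfg)
  expect_equal(m1$rho, 6)
  expect_equal(m1$rho_u, 0)
  m2 <- lbm_moments(matrix(c(3, 0, 0), 1, 3), cfg)
  expect_equal(m2$rho, 3)
  expect_equal(m2$rho_u, -3)
  m0 <- lbm_moments(matrix(0, 5, 3), cfg)
  expect_equal(m0$h_phys, cbind(rho = numeric(5), rho_u = numeric(5)))
})

test_that("global mass is conserved through full collide-stream evolution", {
  cfg <- lbm_config(n_steps = 6)
  pars <- lbm_init_params(cfg, seed = 9)
  pars$coll_A <- matrix(stats::rnorm(9, sd = 0.3), 3, 3)
  c_win <- stats::rnorm(64)
  F0 <- lbm_lift(c_win, pars$lift_W, pars$lift_b)
  out <- lbm_encode(c_win, pars, cfg)
  expect_equal(sum(out$rho), sum(F0), tolerance = 1e-9)
})

test_that("encode with K = 0 reduces to moments of the lifted state", {
  cfg0 <- lbm_config(n_steps = 0)
  pars <- lbm_init_params(cfg0, seed = 2)
  c_win <- stats::rnorm(32)
  out <- lbm_encode(c_win, pars, cfg0)
  direct <- lbm_moments(lbm_lift(c_win, pars$lift_W, pars$lift_b), cfg0)
  expect_equal(out, direct)
})

test_that("encode composes oracles when collision is the identity", {
  cfg <- lbm_config(n_steps = 3)
  pars <- lbm_init_params(cfg, seed = 5)   # coll_A is zero at init
  c_win <- stats::rnorm(32)
  F <- lbm_lift(c_win, pars$lift_W, pars$lift_b)
  for (k in 1:3) F <- lbm_stream(F, cfg)
  expect_equal(lbm_encode(c_win, pars, cfg)$h_phys,
               lbm_moments(F, cfg)$h_phys)
})

test_that("degenerate velocity sets are rejected", {
  expect_error(lbm_config(Q = 1L, velocities = 0L), "degenerate")
})

test_that("batched autodiff encoder matches the plain encoder", {
  cfg <- lbm_config(n_steps = 4)
  pars <- lbm_init_params(cfg, seed = 3)
  pars$coll_A <- matrix(stats::rnorm(9, sd = 0.2), 3, 3)
  set.seed(8)
  B <- 3L; L <- 32L
  ppg <- matrix(stats::rnorm(L * B), L, B)
  geom <- physdiff:::ad_geom(L, B)
  leaves <- list(lift_W = physdiff:::ad_leaf(matrix(pars$lift_W, 1, 3)),
                 lift_b = physdiff:::ad_leaf(pars$lift_b),
                 coll_A = physdiff:::ad_leaf(pars$coll_A),
                 coll_a = physdiff:::ad_leaf(pars$coll_a))
  h <- physdiff:::vl(physdiff:::lbm_encode_ad(
    physdiff:::ad_const(matrix(as.numeric(ppg), ncol = 1)),
    leaves, cfg, geom))
  for (b in seq_len(B)) {
    plain <- lbm_encode(ppg[, b], pars, cfg)$h_phys
    rows <- ((b - 1) * L + 1):(b * L)
    expect_equal(unname(h[rows, ]), unname(plain), tolerance = 1e-12)
  }
})
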