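# Reverse-mode autodiff engine: every structural op is checked against
# central finite differences on random instances.

ad <- function(name) get(name, asNamespace("physdiff"))

# numeric gradient of scalar-valued f (builds the graph itself) w.r.t. a
# parameter matrix P, compared entry-wise
check_grad <- function(build, P, tol = 1e-6, h = 1e-6) {
  ad("ad_begin")()
  leaf <- ad("ad_leaf")(P)
  loss <- build(leaf)
  ad("ad_backward")(loss)
  g_auto <- leaf$grad
  ad("ad_end")()
  g_num <- P * 0
  for (i in seq_along(P)) {
    Pp <- P; Pp[i] <- Pp[i] + h
    Pm <- P; Pm[i] <- Pm[i] - h
    ad("ad_begin")()
    fp <- ad("vl")(build(ad("ad_leaf")(Pp)))[1]
    ad("ad_end")()
    ad("ad_begin")()
    fm <- ad("vl")(build(ad("ad_leaf")(Pm)))[1]
    ad("ad_end")()
    g_num[i] <- (fp - fm) / (2 * h)
  }
  expect_lt(max(abs(g_auto - g_num)) / max(max(abs(g_num)), 1e-8), tol)
}

test_that("elementwise ops, matmul and activations backpropagate correctly", {
  set.seed(1)
  A <- matrix(stats::rnorm(12), 4, 3)
  Bm <- matrix(stats::rnorm(12), 3, 4)
  tgt <- matrix(stats::rnorm(16), 4, 4)
  check_grad(function(p) ad("ad_mse")(ad("ad_matmul")(p, ad("ad_const")(Bm)),
                                      ad("ad_const")(tgt)), A)
  check_grad(function(p) ad("ad_mean")(ad("ad_silu")(p)), A, h = 1e-5)
  check_grad(function(p) ad("ad_mean")(ad("ad_softplus")(p)), A, h = 1e-5)
  check_grad(function(p) ad("ad_mean")(
    ad("ad_mul")(ad("ad_sigmoid")(p), ad("ad_const")(A + 1))), A, h = 1e-5)
  check_grad(function(p) ad("ad_mse")(ad("ad_softmax_rows")(
    ad("ad_mul")(p, ad("ad_const")(tgt[1:4, 1:3]))),
    ad("ad_const")(tgt[1:4, 1:3])), A, h = 1e-5)
  bias <- matrix(stats::rnorm(3), 3, 1)
  check_grad(function(p) ad("ad_mean")(ad("ad_addbias")(
    ad("ad_const")(A), p)), bias)
})

test_that("bce matches its formula and gradient", {
  set.seed(2)
  r <- matrix(rbinom(12, 1, 0.5), 6, 2)
  P0 <- matrix(stats::runif(12, 0.05, 0.95), 6, 2)
  ad("ad_begin")()
  val <- ad("vl")(ad("ad_bce")(ad("ad_leaf")(P0), ad("ad_const")(r)))[1]
  ad("ad_end")()
  expect_equal(val, -mean(r * log(P0) + (1 - r) * log(1 - P0)),
               tolerance = 1e-12)
  check_grad(function(p) ad("ad_bce")(p, ad("ad_const")(r)), P0, h = 1e-7)
})

test_that("structural ops (conv, pool, upsample, shift, tdiff) backprop", {
  set.seed(3)
  L <- 8L; B <- 2L; C <- 3L
  geom <- ad("ad_geom")(L, B)
  X <- matrix(stats::rnorm(L * B * C), L * B, C)
  W <- matrix(stats::rnorm(3 * C * 2), 3 * C, 2)
  bb <- matrix(0.1, 2, 1)
  tgt <- matrix(stats::rnorm(L * B * 2), L * B, 2)
  # gradient w.r.t. the input
  check_grad(function(p) ad("ad_mse")(
    ad("ad_conv1d")(p, ad("ad_const")(W), ad("ad_const")(bb), geom),
    ad("ad_const")(tgt)), X)
  # gradient w.r.t. the kernel
  check_grad(function(p) ad("ad_mse")(
    ad("ad_conv1d")(ad("ad_const")(X), p, ad("ad_const")(bb), geom),
    ad("ad_const")(tgt)), W)
  tgt_half <- matrix(stats::rnorm(L * B / 2 * C), L * B / 2, C)
  check_grad(function(p) ad("ad_mse")(ad("ad_avgpool2")(p, geom),
                                      ad("ad_const")(tgt_half)), X)
  geom_half <- ad("ad_geom")(L %/% 2L, B)
  Xh <- matrix(stats::rnorm(L * B / 2 * C), L * B / 2, C)
  check_grad(function(p) ad("ad_mse")(ad("ad_upsample2")(p, geom_half),
                                      ad("ad_const")(X)), Xh)
  check_grad(function(p) ad("ad_mse")(
    ad("ad_shift_circ")(p, c(-1L, 0L, 1L), geom), ad("ad_const")(X)), X)
  check_grad(function(p) ad("ad_mse")(ad("ad_tdiff")(p, geom),
                                      ad("ad_const")(X)), X)
})

test_that("group normalization matches statistics and backpropagates", {
  set.seed(4)
  L <- 8L; B <- 2L; C <- 4L; G <- 2L
  geom <- ad("ad_geom")(L, B)
  X <- matrix(stats::rnorm(L * B * C, sd = 2), L * B, C)
  gamma <- matrix(stats::runif(C, 0.5, 1.5), C, 1)
  beta <- matrix(stats::rnorm(C, sd = 0.2), C, 1)
  ad("ad_begin")()
  Y <- ad("vl")(ad("ad_groupnorm")(ad("ad_leaf")(X), ad("ad_const")(gamma),
                                   ad("ad_const")(beta), G, geom))
  ad("ad_end")()
  # per (element, group) statistics of the normalized features
  xhat <- (Y - rep(as.numeric(beta), each = L * B)) /
    rep(as.numeric(gamma), each = L * B)
  blk <- xhat[1:L, 1:2]
  expect_equal(mean(blk), 0, tolerance = 1e-8)
  expect_equal(stats::sd(as.numeric(blk)) *
                 sqrt((length(blk) - 1) / length(blk)), 1, tolerance = 1e-3)
  tgt <- matrix(stats::rnorm(L * B * C), L * B, C)
  check_grad(function(p) ad("ad_mse")(
    ad("ad_groupnorm")(p, ad("ad_const")(gamma), ad("ad_const")(beta),
                       G, geom), ad("ad_const")(tgt)), X, tol = 1e-5)
  check_grad(function(p) ad("ad_mse")(
    ad("ad_groupnorm")(ad("ad_const")(X), p, ad("ad_const")(beta),
                       G, geom), ad("ad_const")(tgt)), gamma)
})

test_that("streaming and pooling are exact permutations/averages", {
  set.seed(5)
  L <- 6L; B <- 2L
  geom <- ad("ad_geom")(L, B)
  X <- matrix(stats::rnorm(L * B * 3), L * B, 3)
  ad("ad_begin")()
  Y <- ad("vl")(ad("ad_shift_circ")(ad("ad_leaf")(X), c(-1L, 0L, 1L), geom))
  ad("ad_end")()
  expect_equal(colSums(Y), colSums(X))                 # permutation
  expect_equal(Y[1:L, 2], X[1:L, 2])                   # stationary channel
  expect_equal(Y[2:L, 3], X[1:(L - 1), 3])             # +1 advection
  expect_equal(Y[1, 3], X[L, 3])                       # periodic wrap
})
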