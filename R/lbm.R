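# Implicit lattice-Boltzmann (D1Q3) physics encoder.
#
# The PPG window is lifted into Q non-negative mesoscopic distribution
# channels, evolved by K learnable collide-and-stream iterations, and read
# out as macroscopic moments (density rho, momentum rho*u) that form the
# conditioning embedding h_phys.  The collision residual comes from a
# learned channel-mixing (1x1) linear map; a moment projection subtracts its
# per-site mass and momentum excess so both are conserved exactly.

#' Lattice configuration for the physics encoder
#'
#' @param Q Number of discrete velocity channels (default 3, D1Q3).
#' @param velocities Integer lattice velocities (default `c(-1, 0, 1)`).
#' @param stride Samples advected per streaming step and unit velocity.
#' @param n_steps Number of collide-and-stream iterations `K`.
#' @param projection `"exact"` subtracts the momentum excess with
#'   coefficient `e_i / sum(e^2)`, which zeroes both moments for any
#'   zero-sum velocity set; `"three_over_q"` uses coefficient `3 e_i / Q`
#'   (kept for comparison; it does not zero the first moment for D1Q3).
#' @return An object of class `"lbm_config"`.
#' @export
lbm_config <- function(Q = 3L, velocities = c(-1L, 0L, 1L), stride = 1L,
                       n_steps = 4L,
                       projection = c("exact", "three_over_q")) {
  projection <- match.arg(projection)
  stopifnot(Q == length(velocities), !anyDuplicated(velocities),
            stride >= 1, n_steps >= 0)
  if (projection == "exact" && sum(velocities^2) == 0)
    stop("degenerate velocity set: sum(e^2) = 0")
  structure(list(Q = as.integer(Q), velocities = as.integer(velocities),
                 stride = as.integer(stride), n_steps = as.integer(n_steps),
                 projection = projection),
            class = "lbm_config")
}

#' Lift a signal window into mesoscopic distributions
#'
#' `F_i(x) = softplus(W_i c(x) + b_i)`; the softplus keeps every
#' distribution value strictly positive.
#'
#' @param c_win Length-L numeric window.
#' @param W Length-Q lifting weights.
#' @param b Length-Q lifting biases.
#' @return An L x Q matrix of strictly positive distribution values.
#' @export
lbm_lift <- function(c_win, W, b) {
  stopifnot(all(is.finite(c_win)), length(W) == length(b))
  .softplus(outer(as.numeric(c_win), as.numeric(W)) +
              rep(as.numeric(b), each = length(c_win)))
}

#' Apply the learned collision with exact moment projection
#'
#' The raw residual is a per-site channel mix `Ctilde = F A + a`.  The
#' projection subtracts, per site, the mass excess `sum_i Ctilde_i`
#' (uniformly, `/Q`) and the momentum excess `sum_i e_i Ctilde_i` (along
#' `e`, with coefficient `e_i / sum(e^2)` for `"exact"` or `3 e_i / Q` for
#' `"three_over_q"`), then returns `F + C`.
#'
#' @param F L x Q distribution matrix.
#' @param A Q x Q channel-mixing matrix.
#' @param a Length-Q residual bias.
#' @param config An [lbm_config()].
#' @return The post-collision L x Q distribution matrix.
#' @export
lbm_collide <- function(F, A, a, config = lbm_config()) {
  stopifnot(all(is.finite(F)), ncol(F) == config$Q)
  Ct <- F %*% A + rep(as.numeric(a), each = nrow(F))
  F + lbm_project_residual(Ct, config)
}

#' Project a raw collision residual onto the conserving subspace
#'
#' @param Ct L x Q raw residual matrix.
#' @param config An [lbm_config()].
#' @return The projected residual, whose per-site mass and momentum sums
#'   vanish (exactly, under `projection = "exact"`).
#' @export
lbm_project_residual <- function(Ct, config = lbm_config()) {
  e <- config$velocities
  drho <- rowSums(Ct)
  dm <- as.numeric(Ct %*% e)
  coef <- if (config$projection == "exact") e / sum(e^2) else 3 * e / config$Q
  Ct - outer(drho, rep(1 / config$Q, config$Q)) - outer(dm, coef)
}

#' Stream distributions along their lattice velocities
#'
#' Channel `k` is circularly shifted by `e_k * stride` samples (periodic
#' boundary); the stationary channel is unchanged.
#'
#' @param F L x Q distribution matrix.
#' @param config An [lbm_config()].
#' @return The streamed L x Q matrix.
#' @export
lbm_stream <- function(F, config = lbm_config()) {
  stopifnot(all(is.finite(F)))
  L <- nrow(F)
  out <- F
  for (k in seq_len(config$Q)) {
    s <- (config$velocities[k] * config$stride) %% L
    if (s == 0) next
    src <- ((seq_len(L) - 1L - s) %% L) + 1L
    out[, k] <- F[src, k]
  }
  out
}

#' Macroscopic moments of a distribution state
#'
#' @param F L x Q distribution matrix.
#' @param config An [lbm_config()].
#' @return A list with `rho` (zeroth moment, length L), `rho_u` (first
#'   moment), and `h_phys` (their L x 2 column concatenation).
#' @export
lbm_moments <- function(F, config = lbm_config()) {
  rho <- rowSums(F)
  rho_u <- as.numeric(F %*% config$velocities)
  list(rho = rho, rho_u = rho_u, h_phys = cbind(rho = rho, rho_u = rho_u))
}

#' Initialize encoder parameters
#'
#' The collision mix starts at zero (identity collision); lifting weights
#' are small random values.
#'
#' @param config An [lbm_config()].
#' @param seed Integer seed.
#' @return Named list of parameter arrays (`lift_W`, `lift_b`, `coll_A`,
#'   `coll_a`).
#' @export
lbm_init_params <- function(config = lbm_config(), seed = 1L) {
  rng <- make_rng(seed)
  Q <- config$Q
  list(lift_W = rng$rnorm(Q, sd = 0.5),
       lift_b = rep(0.1, Q),
       coll_A = matrix(0, Q, Q),
       coll_a = rep(0, Q))
}

#' Encode a PPG window into hemodynamic conditioning features
#'
#' Lift, then `K` collide-and-stream iterations, then moments.
#'
#' @param c_win Length-L numeric PPG window.
#' @param params Encoder parameters ([lbm_init_params()]).
#' @param config An [lbm_config()].
#' @return As [lbm_moments()].
#' @export
lbm_encode <- function(c_win, params, config = lbm_config()) {
  F <- lbm_lift(c_win, params$lift_W, params$lift_b)
  if (config$n_steps > 0) {
    for (k in seq_len(config$n_steps)) {
      F <- lbm_collide(F, params$coll_A, params$coll_a, config)
      F <- lbm_stream(F, config)
    }
  }
  lbm_moments(F, config)
}

## ---- autodiff-graph version (batched, used by training) ----

# c_node: (B*L) x 1 node; pars: list of ad leaves lift_W (1xQ), lift_b (Q),
# coll_A (QxQ), coll_a (Q).  Returns the (B*L) x 2 h_phys node.
lbm_encode_ad <- function(c_node, pars, config, geom) {
  e <- matrix(as.numeric(config$velocities), ncol = 1L)
  Q <- config$Q
  Fn <- ad_softplus(ad_addbias(ad_matmul(c_node, pars$lift_W), pars$lift_b))
  if (config$n_steps > 0) {
    ones <- matrix(1, Q, 1L)
    coef <- if (config$projection == "exact") e / sum(e^2) else 3 * e / Q
    shifts <- config$velocities * config$stride
    for (k in seq_len(config$n_steps)) {
      Ct <- ad_addbias(ad_matmul(Fn, pars$coll_A), pars$coll_a)
      drho <- ad_matmul(Ct, ad_const(ones))            # (B*L) x 1
      dm <- ad_matmul(Ct, ad_const(e))
      C <- ad_sub(Ct, ad_add(ad_matmul(drho, ad_const(t(ones) / Q)),
                             ad_matmul(dm, ad_const(t(coef)))))
      Fn <- ad_add(Fn, C)
      Fn <- ad_shift_circ(Fn, shifts, geom)
    }
  }
  rho <- ad_matmul(Fn, ad_const(matrix(1, Q, 1L)))
  rho_u <- ad_matmul(Fn, ad_const(e))
  ad_cbind(rho, rho_u)
}
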