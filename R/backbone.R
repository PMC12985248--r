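# Region-disentangled 1D U-Net denoiser.
#
# A shared multiscale encoder-decoder over the noisy ECG (conditioned on
# the timestep embedding and, at the bottleneck, on the hemodynamic
# features via cross-attention) feeds two heads: the geometry head emits
# the predicted noise eps_hat, the topology head emits a QRS-region
# probability mask r_hat through a sigmoid.

#' Backbone configuration
#'
#' @param L Window length in samples; must be divisible by
#'   `2^(n_scales - 1)`.
#' @param base_width Channel count at the top resolution; deeper levels
#'   double it.
#' @param n_scales Number of resolution levels (depth).
#' @param n_blocks Residual blocks per level (the first changes the
#'   channel count, the rest preserve it).
#' @param attention_dim Attention key dimension `d_k`; defaults to the
#'   bottleneck channel count (in which case the attended values add
#'   directly onto the bottleneck features, without an output projection).
#' @param groups Groups for the group normalization in the geometry head.
#' @param temb_dim Timestep embedding dimension (even).
#' @param concat_condition Also concatenate `h_phys` to the network input
#'   (the bottleneck cross-attention is always applied).
#' @param head_param Parameterization of the geometry head: `"x0"`
#'   (default) predicts the clean signal and recovers the noise residual
#'   `eps_hat = (x_t - sqrt(ab_t) x0_hat) / sqrt(1 - ab_t)` algebraically —
#'   the head's target is then timestep-independent, which trains far
#'   faster at small step budgets; `"eps"` emits the noise residual
#'   directly from the convolutional head.
#' @return An object of class `"backbone_config"`.
#' @export
backbone_config <- function(L = 512L, base_width = 32L, n_scales = 3L,
                            n_blocks = 2L, attention_dim = NULL,
                            groups = 4L, temb_dim = 32L,
                            concat_condition = TRUE,
                            head_param = c("x0", "eps")) {
  head_param <- match.arg(head_param)
  stopifnot(n_blocks >= 1L)
  stopifnot(n_scales >= 1, L %% (2^(n_scales - 1)) == 0,
            temb_dim %% 2 == 0, base_width %% groups == 0)
  # channel plan: double once below the top level, then hold constant
  widths <- as.integer(base_width * 2^pmin(seq_len(n_scales) - 1L, 1L))
  if (is.null(attention_dim)) attention_dim <- widths[n_scales]
  structure(list(L = as.integer(L), base_width = as.integer(base_width),
                 n_scales = as.integer(n_scales), widths = widths,
                 attention_dim = as.integer(attention_dim),
                 groups = as.integer(groups),
                 temb_dim = as.integer(temb_dim),
                 n_blocks = as.integer(n_blocks),
                 concat_condition = isTRUE(concat_condition),
                 head_param = head_param),
            class = "backbone_config")
}

#' Sinusoidal timestep embedding
#'
#' Standard position encoding: `[sin(t w_1), ..., cos(t w_1), ...]` with
#' geometrically spaced frequencies.  The backbone applies a small learned
#' two-layer map on top of this fixed encoding.
#'
#' @param t Non-negative integer timestep(s).
#' @param dim Embedding dimension (even, >= 4).
#' @return A `length(t)` x `dim` matrix.
#' @export
embed_timestep <- function(t, dim = 32L) {
  stopifnot(dim %% 2 == 0, dim >= 4)
  if (any(t < 0)) stop("timestep t out of range (must be >= 0)")
  half <- dim %/% 2L
  freqs <- 10000^(-(seq_len(half) - 1L) / (half - 1L))
  ang <- outer(as.numeric(t), freqs)
  cbind(sin(ang), cos(ang))
}

#' Physics-guided cross-attention
#'
#' `Q = Z W_Q`, `K = h W_K`, `V = h W_V`;
#' `Z' = Z + softmax(Q K^T / sqrt(d_k)) V`.  Row-softmax makes each row of
#' the attention matrix a probability distribution over hemodynamic
#' positions.
#'
#' @param Z Bottleneck feature matrix (L' x D_z).
#' @param h_phys Downsampled hemodynamic features (L' x D_p).
#' @param W_Q D_z x d_k query projection.
#' @param W_K,W_V D_p x d_k key/value projections (`d_k` must equal `D_z`
#'   for the residual sum).
#' @return A list with `Z_prime` (L' x D_z) and `attention` (L' x L',
#'   rows summing to 1).
#' @export
cross_attention <- function(Z, h_phys, W_Q, W_K, W_V) {
  stopifnot(nrow(Z) == nrow(h_phys))
  Qm <- Z %*% W_Q
  Km <- h_phys %*% W_K
  Vm <- h_phys %*% W_V
  dk <- ncol(Qm)
  S <- Qm %*% t(Km) / sqrt(dk)
  S <- S - apply(S, 1L, max)
  M <- exp(S) / rowSums(exp(S))
  list(Z_prime = Z + M %*% Vm, attention = M)
}

#' Initialize backbone parameters
#'
#' Hidden convolutions use He initialization; both output heads start
#' near zero (setting them exactly to zero makes an untrained backbone
#' emit `eps_hat = 0` and `r_hat = 0.5`).
#'
#' @param cfg A [backbone_config()].
#' @param seed Integer seed.
#' @param cond_dim Channel count of `h_phys` (2: density and momentum).
#' @return Named list of parameter arrays.
#' @export
backbone_init_params <- function(cfg, seed = 1L, cond_dim = 2L) {
  rng <- make_rng(seed)
  K <- 3L
  he <- function(nin, nout) matrix(rng$rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  p <- list()
  d_t <- cfg$temb_dim
  p$temb_W1 <- he(d_t, d_t); p$temb_b1 <- rep(0, d_t)
  p$temb_W2 <- he(d_t, d_t); p$temb_b2 <- rep(0, d_t)
  # pre-norm residual block: gn1 -> SiLU -> conv1 -> +temb -> gn2 -> SiLU
  # -> conv2 (near-zero) + skip (1x1 projection on channel change)
  block <- function(prefix, cin, w) {
    p[[paste0(prefix, "_g1")]] <<- rep(1, cin)
    p[[paste0(prefix, "_be1")]] <<- rep(0, cin)
    p[[paste0(prefix, "_W1")]] <<- he(K * cin, w)
    p[[paste0(prefix, "_b1")]] <<- rep(0, w)
    p[[paste0(prefix, "_tW")]] <<- he(d_t, w)
    p[[paste0(prefix, "_tb")]] <<- rep(0, w)
    p[[paste0(prefix, "_g2")]] <<- rep(1, w)
    p[[paste0(prefix, "_be2")]] <<- rep(0, w)
    p[[paste0(prefix, "_W2")]] <<- matrix(rng$rnorm(K * w * w, sd = 0.01),
                                          K * w, w)
    p[[paste0(prefix, "_b2")]] <<- rep(0, w)
    if (cin != w) p[[paste0(prefix, "_Ws")]] <<- he(cin, w)
  }
  cin <- 1L + if (cfg$concat_condition) cond_dim else 0L
  for (i in seq_len(cfg$n_scales)) {
    block(paste0("down", i), cin, cfg$widths[i])
    for (j in seq_len(cfg$n_blocks - 1L))
      block(paste0("down", i, "x", j + 1L), cfg$widths[i], cfg$widths[i])
    cin <- cfg$widths[i]
  }
  dz <- cfg$widths[cfg$n_scales]
  dk <- cfg$attention_dim
  p$attn_WQ <- matrix(rng$rnorm(dz * dk, sd = 1 / sqrt(dz)), dz, dk)
  p$attn_WK <- matrix(rng$rnorm(cond_dim * dk, sd = 1 / sqrt(cond_dim)),
                      cond_dim, dk)
  p$attn_WV <- matrix(rng$rnorm(cond_dim * dk, sd = 1 / sqrt(cond_dim)),
                      cond_dim, dk)
  if (dk != dz) p$attn_WO <- matrix(rng$rnorm(dk * dz, sd = 1 / sqrt(dk)),
                                    dk, dz)
  Lp <- cfg$L %/% (2L^(cfg$n_scales - 1L))
  p$attn_rel <- matrix(0, 2L * Lp - 1L, 1L)   # relative-position logit bias
  if (cfg$n_scales > 1L) {
    for (i in seq(cfg$n_scales - 1L, 1L)) {
      block(paste0("up", i), cfg$widths[i + 1L] + cfg$widths[i],
            cfg$widths[i])
      for (j in seq_len(cfg$n_blocks - 1L))
        block(paste0("up", i, "x", j + 1L), cfg$widths[i], cfg$widths[i])
    }
  }
  w1 <- cfg$widths[1L]
  p$gn_gamma <- rep(1, w1); p$gn_beta <- rep(0, w1)
  # near-zero heads: outputs start close to (0, 0.5) while keeping every
  # upstream gradient path live from the first step
  p$head_eps_W <- matrix(rng$rnorm(K * w1, sd = 0.01), K * w1, 1L)
  p$head_eps_b <- 0
  p$head_mask_W <- matrix(rng$rnorm(K * w1, sd = 0.01), K * w1, 1L)
  p$head_mask_b <- 0
  # learned per-timestep gate on the long skip x_t -> eps_hat: the noisy
  # input's direct contribution to the noise estimate is handled here, so
  # the convolutional head only needs the condition-driven correction
  p$head_skip <- matrix(0, cfg$temb_dim, 1L)
  p
}

# per-window skip-gate coefficients from the timestep embedding
.skip_gate_ad <- function(t_vec, pars, cfg, sched_hint = NULL) {
  ad_matmul(ad_const(embed_timestep(t_vec, cfg$temb_dim)), pars$head_skip)
}

# Geometry caches for each resolution level of a fixed (L, B).
backbone_geoms <- function(cfg, B) {
  lapply(seq_len(cfg$n_scales), function(i)
    ad_geom(cfg$L %/% (2L^(i - 1L)), B))
}

# Build the backbone forward graph.
# x_node: (B*L) x 1 noisy ECG; t_vec: length-B integer timesteps;
# h_node: (B*L) x 2 hemodynamic features; pars: list of ad leaves.
# Returns list(eps_hat, r_hat, h_dec) of ad nodes.
# largest divisor of C not exceeding g
.gn_groups <- function(C, g) {
  for (k in seq(min(g, C), 1L)) if (C %% k == 0L) return(k)
  1L
}

# pre-norm residual block with timestep conditioning
.resblock_ad <- function(h, prefix, pars, temb, g, groups) {
  C_in <- ncol(vl(h))
  r <- ad_groupnorm(h, pars[[paste0(prefix, "_g1")]],
                    pars[[paste0(prefix, "_be1")]],
                    .gn_groups(C_in, groups), g)
  r <- ad_conv1d(ad_silu(r), pars[[paste0(prefix, "_W1")]],
                 pars[[paste0(prefix, "_b1")]], g)
  ei <- ad_addbias(ad_matmul(temb, pars[[paste0(prefix, "_tW")]]),
                   pars[[paste0(prefix, "_tb")]])
  r <- ad_addrows(r, ei, g$blockid)
  C_out <- ncol(vl(r))
  r <- ad_silu(ad_groupnorm(r, pars[[paste0(prefix, "_g2")]],
                            pars[[paste0(prefix, "_be2")]],
                            .gn_groups(C_out, groups), g))
  r <- ad_conv1d(r, pars[[paste0(prefix, "_W2")]],
                 pars[[paste0(prefix, "_b2")]], g)
  skip <- if (!is.null(pars[[paste0(prefix, "_Ws")]]))
    ad_matmul(h, pars[[paste0(prefix, "_Ws")]]) else h
  ad_add(skip, r)
}

# tw: NULL for the "eps" head, else list(sa, s1) of per-window
# sqrt(alpha_bar_t) and sqrt(1 - alpha_bar_t) expanded to stacked rows
backbone_forward_ad <- function(x_node, t_vec, h_node, pars, cfg, geoms,
                                tw = NULL) {
  B <- geoms[[1L]]$B
  temb0 <- ad_const(embed_timestep(t_vec, cfg$temb_dim))
  temb <- ad_addbias(ad_matmul(
    ad_silu(ad_addbias(ad_matmul(temb0, pars$temb_W1), pars$temb_b1)),
    pars$temb_W2), pars$temb_b2)          # B x d_t
  h <- if (cfg$concat_condition) ad_cbind(x_node, h_node) else x_node
  skips <- vector("list", cfg$n_scales)
  for (i in seq_len(cfg$n_scales)) {
    h <- .resblock_ad(h, paste0("down", i), pars, temb, geoms[[i]],
                      cfg$groups)
    for (j in seq_len(cfg$n_blocks - 1L))
      h <- .resblock_ad(h, paste0("down", i, "x", j + 1L), pars, temb,
                        geoms[[i]], cfg$groups)
    skips[[i]] <- h
    if (i < cfg$n_scales) h <- ad_avgpool2(h, geoms[[i]])
  }
  # bottleneck cross-attention against pooled h_phys
  gb <- geoms[[cfg$n_scales]]
  hp <- h_node
  if (cfg$n_scales > 1L)
    for (i in seq_len(cfg$n_scales - 1L)) hp <- ad_avgpool2(hp, geoms[[i]])
  h <- ad_add(h, attention_block_ad(h, hp, pars, gb))
  if (cfg$n_scales > 1L) {
    for (i in seq(cfg$n_scales - 1L, 1L)) {
      h <- ad_upsample2(h, geoms[[i + 1L]])
      h <- ad_cbind(h, skips[[i]])
      h <- .resblock_ad(h, paste0("up", i), pars, temb, geoms[[i]],
                        cfg$groups)
      for (j in seq_len(cfg$n_blocks - 1L))
        h <- .resblock_ad(h, paste0("up", i, "x", j + 1L), pars, temb,
                          geoms[[i]], cfg$groups)
    }
  }
  h_dec <- h
  g1 <- geoms[[1L]]
  geo <- ad_silu(ad_groupnorm(h_dec, pars$gn_gamma, pars$gn_beta,
                              cfg$groups, g1))
  y <- ad_conv1d(geo, pars$head_eps_W, pars$head_eps_b, g1)
  if (!is.null(pars$head_skip)) {
    gate <- .skip_gate_ad(t_vec, pars, cfg)           # B x 1
    y <- ad_add(y, ad_mul(ad_rows(gate, g1$blockid), x_node))
  }
  if (cfg$head_param == "x0") {
    if (is.null(tw)) stop("x0-parameterized head needs schedule coefficients")
    x0_hat <- y
    eps_hat <- ad_mul(ad_sub(x_node, ad_mul(x0_hat, ad_const(tw$sa))),
                      ad_const(1 / tw$s1))
  } else {
    eps_hat <- y
    x0_hat <- if (is.null(tw)) NULL else
      ad_mul(ad_sub(x_node, ad_mul(eps_hat, ad_const(tw$s1))),
             ad_const(1 / tw$sa))
  }
  r_hat <- ad_sigmoid(ad_conv1d(h_dec, pars$head_mask_W,
                                pars$head_mask_b, g1))
  list(eps_hat = eps_hat, r_hat = r_hat, x0_hat = x0_hat, h_dec = h_dec)
}

# the attention contribution (to be added to the bottleneck features).
# A learnable relative-position bias on the logits lets the layer express
# the roughly constant electro-mechanical lag (PTT) directly; the
# content term Q K^T can then sharpen the alignment per window.
attention_block_ad <- function(Z, hp, pars, gb) {
  dk <- ncol(vl(pars$attn_WQ))
  outs <- vector("list", gb$B)
  for (b in seq_len(gb$B)) {
    rows <- ((b - 1L) * gb$L + 1L):(b * gb$L)
    Zb <- ad_rows(Z, rows)
    Hb <- ad_rows(hp, rows)
    Qb <- ad_matmul(Zb, pars$attn_WQ)
    Kb <- ad_matmul(Hb, pars$attn_WK)
    Vb <- ad_matmul(Hb, pars$attn_WV)
    logits <- ad_smul(ad_matmul(Qb, ad_transpose(Kb)), 1 / sqrt(dk))
    if (!is.null(pars$attn_rel))
      logits <- ad_relbias(logits, pars$attn_rel, gb$L)
    M <- ad_softmax_rows(logits)
    A <- ad_matmul(M, Vb)
    if (!is.null(pars$attn_WO)) A <- ad_matmul(A, pars$attn_WO)
    outs[[b]] <- A
  }
  if (gb$B == 1L) outs[[1L]] else ad_rbind(outs)
}

#' Run the backbone on a batch of windows (no gradient recording)
#'
#' @param x_t L x B matrix of noisy ECG windows (one column per window).
#' @param t_vec Length-B integer timesteps.
#' @param h_phys (B*L) x 2 matrix of hemodynamic features (stacked rows).
#' @param pars Backbone parameters ([backbone_init_params()]).
#' @param cfg A [backbone_config()].
#' @param sched A [noise_schedule()]; required for the `"x0"` head
#'   parameterization (supplies the per-timestep coefficients that link
#'   `x0_hat` and `eps_hat`).
#' @return A list with `eps_hat`, `r_hat` (L x B matrices), `x0_hat`
#'   (L x B or `NULL` when no schedule is given), and `h_dec`.
#' @export
backbone_forward <- function(x_t, t_vec, h_phys, pars, cfg, sched = NULL) {
  x_t <- as_mat(x_t)
  B <- ncol(x_t)
  stopifnot(nrow(x_t) == cfg$L, nrow(h_phys) == B * cfg$L)
  geoms <- backbone_geoms(cfg, B)
  leaves <- lapply(pars, ad_leaf)
  tw <- if (!is.null(sched))
    list(sa = rep(sqrt(sched$alpha_bar[t_vec]), each = cfg$L),
         s1 = rep(sqrt(1 - sched$alpha_bar[t_vec]), each = cfg$L))
  out <- backbone_forward_ad(ad_const(matrix(as.numeric(x_t), ncol = 1L)),
                             t_vec, ad_const(h_phys), leaves, cfg, geoms,
                             tw = tw)
  list(eps_hat = matrix(vl(out$eps_hat), cfg$L, B),
       r_hat = matrix(vl(out$r_hat), cfg$L, B),
       x0_hat = if (!is.null(out$x0_hat))
         matrix(vl(out$x0_hat), cfg$L, B),
       h_dec = vl(out$h_dec))
}
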