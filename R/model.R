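# The physdiff model: joint training of the lattice-Boltzmann encoder, the
# dual-branch U-Net denoiser, and the physics projection head under the
# composite diffusion objective; classic fit-object interface.

#' Fit a physics-aware PPG-to-ECG diffusion model
#'
#' Trains, with Adam, the lattice-Boltzmann encoder, the dual-branch U-Net
#' and the physics projection head jointly: each step draws a minibatch of
#' windows, a uniform timestep per window and Gaussian noise, corrupts the
#' ECG, encodes the paired PPG into hemodynamic features, and minimizes
#' `lambda_diff * L_diff + lambda_reg * L_reg + lambda_phys * L_phys`.
#'
#' @param windows A list of signal windows from [make_windows()] (windows
#'   flagged degenerate are dropped).
#' @param steps Number of optimizer steps (0 returns the untrained model).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param T_steps Diffusion steps; the schedule endpoints are scaled with
#'   `1000 / T` ([noise_schedule_scaled()]).
#' @param weights A [loss_weights()].
#' @param base_width,n_scales Backbone size ([backbone_config()]).
#' @param lbm An [lbm_config()].
#' @param concat_condition Concatenate `h_phys` to the backbone input in
#'   addition to the bottleneck cross-attention.
#' @param head_param Geometry-head parameterization (see
#'   [backbone_config()]); `"x0"` trains the head on the clean-signal
#'   scale and is the default.
#' @param phys_target_detach Treat the physics-loss target `P(h_phys)` as
#'   fixed (no gradient into the encoder through the target).
#' @param ema_decay Decay of the exponential moving average of the
#'   parameters kept alongside the optimized ones and used at inference.
#' @param clip_grad Global gradient-norm clip applied before each Adam
#'   update.
#' @param snr_cap Cap on the inverse-signal-to-noise weight of the
#'   denoising loss (the per-timestep eps error is weighted by
#'   `min((1-ab_t)/ab_t, snr_cap)`, normalized per batch).
#' @param seed Integer seed governing initialization and every draw.
#' @param verbose Print a loss line every `log_every` steps.
#' @param log_every Logging cadence in steps.
#' @return An object of class `"physdiff"`.
#' @export
physdiff <- function(windows, steps = 500L, batch_size = 16L, lr = 2e-3,
                     T_steps = 50L, weights = loss_weights(),
                     base_width = 16L, n_scales = 5L, lbm = lbm_config(),
                     concat_condition = TRUE, phys_target_detach = FALSE,
                     head_param = c("x0", "eps"),
                     ema_decay = 0.99, clip_grad = 1, snr_cap = 5,
                     seed = 1L, verbose = FALSE, log_every = 50L) {
  head_param <- match.arg(head_param)
  windows <- Filter(function(w) !isTRUE(w$degenerate), windows)
  stopifnot(length(windows) >= 1)
  L <- length(windows[[1L]]$ecg)
  cfg <- backbone_config(L = L, base_width = base_width,
                         n_scales = n_scales,
                         concat_condition = concat_condition,
                         head_param = head_param)
  sched <- noise_schedule_scaled(T_steps)
  params <- c(
    .prefix(lbm_init_params(lbm, seed = seed + 1L), "lbm."),
    .prefix(backbone_init_params(cfg, seed = seed + 2L), "bb."),
    list(proj_W = matrix(0, 2L, 1L), proj_b = matrix(0, 1L, 1L)))
  params <- lapply(params, as_mat)
  object <- structure(
    list(params = params, ema = params, ema_decay = ema_decay,
         clip_grad = clip_grad, snr_cap = snr_cap, cfg = cfg,
         lbm = lbm, sched = sched, weights = weights, lr = lr,
         batch_size = batch_size, phys_target_detach = phys_target_detach,
         seed = as.integer(seed), n_windows = length(windows),
         trained_steps = 0L, history = data.frame()),
    class = "physdiff")
  if (steps > 0L)
    object <- physdiff_train(object, windows, steps, verbose = verbose,
                             log_every = log_every)
  object
}

.prefix <- function(lst, p) stats::setNames(lst, paste0(p, names(lst)))

#' Continue training a fitted (or untrained) model
#'
#' @param object A `"physdiff"` object.
#' @param windows Training windows ([make_windows()]).
#' @param steps Additional optimizer steps.
#' @param verbose,log_every Logging controls.
#' @return The updated `"physdiff"` object with extended `history`.
#' @export
physdiff_train <- function(object, windows, steps, verbose = FALSE,
                           log_every = 50L) {
  windows <- Filter(function(w) !isTRUE(w$degenerate), windows)
  L <- object$cfg$L
  stopifnot(all(vapply(windows, function(w) length(w$ecg), 1L) == L))
  N <- length(windows)
  ecg <- vapply(windows, `[[`, numeric(L), "ecg")
  ppg <- vapply(windows, `[[`, numeric(L), "ppg")
  mask <- vapply(windows, function(w) as.numeric(w$mask), numeric(L))
  B <- min(object$batch_size, N)
  geoms <- backbone_geoms(object$cfg, B)
  rng <- make_rng(object$seed + 31L * (object$trained_steps + 1L))
  opt <- .adam_init(object$params, object$lr)
  warmup <- min(50L, max(1L, steps %/% 10L))
  sched <- object$sched
  hist <- vector("list", steps)
  for (step in seq_len(steps)) {
    idx <- rng$sample_int(N, B, replace = N < B)
    tb <- rng$sample_int(sched$T, B)
    eps <- matrix(rng$rnorm(L * B), L, B)
    x0 <- ecg[, idx, drop = FALSE]
    sa <- sqrt(sched$alpha_bar[tb])
    s1 <- sqrt(1 - sched$alpha_bar[tb])
    xt <- sweep(x0, 2L, sa, `*`) + sweep(eps, 2L, s1, `*`)
    ad_begin()
    leaves <- lapply(object$params, ad_leaf)
    losses <- .physdiff_loss_graph(
      leaves, xt, tb, eps, x0, ppg[, idx, drop = FALSE],
      mask[, idx, drop = FALSE], object, geoms)
    ad_backward(losses$total)
    grads <- lapply(leaves, function(l)
      if (is.null(l$grad)) matrix(0, nrow(l$val), ncol(l$val)) else l$grad)
    ad_end()
    # global gradient-norm clipping: the physics term can spike by orders
    # of magnitude at high t (Tweedie amplifies residual noise by
    # 1/sqrt(alpha_bar)); clipping keeps such bursts from wiping the
    # optimizer state
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (is.finite(gnorm) && gnorm > object$clip_grad)
      grads <- lapply(grads, function(g) g * (object$clip_grad / gnorm))
    rec <- c(step = object$trained_steps + step,
             diff = vl(losses$diff)[1], reg = vl(losses$reg)[1],
             phys = vl(losses$phys)[1], total = vl(losses$total)[1])
    if (!all(is.finite(unlist(rec))))
      stop("non-finite loss at step ", step, "; aborting")
    hist[[step]] <- rec
    # linear warmup, then cosine decay to zero over this call's steps
    opt$lr <- object$lr * min(1, step / warmup) *
      0.5 * (1 + cos(pi * max(0, step - warmup) / max(1, steps - warmup)))
    object$params <- .adam_step(opt, object$params, grads)
    d <- object$ema_decay
    object$ema <- Map(function(e, p) d * e + (1 - d) * p,
                      object$ema, object$params)
    if (verbose && (step %% log_every == 0L || step == steps))
      message(sprintf("step %d  L_diff %.4f  L_reg %.4f  L_phys %.4f  total %.4f",
                      rec["step"], rec["diff"], rec["reg"], rec["phys"],
                      rec["total"]))
  }
  object$history <- rbind(object$history,
                          as.data.frame(do.call(rbind, hist)))
  object$trained_steps <- object$trained_steps + steps
  object$n_windows <- N
  object
}

# Build the full loss graph for one minibatch.  All inputs are plain
# matrices except `leaves` (parameter nodes).
.physdiff_loss_graph <- function(leaves, xt, tb, eps, x0_b, ppg_b, mask_b,
                                 object, geoms) {
  cfg <- object$cfg; sched <- object$sched; w <- object$weights
  L <- cfg$L; B <- ncol(xt)
  g1 <- geoms[[1L]]
  stack <- function(m) matrix(as.numeric(m), ncol = 1L)
  lbm_pars <- list(lift_W = ad_transpose(leaves[["lbm.lift_W"]]),
                   lift_b = leaves[["lbm.lift_b"]],
                   coll_A = leaves[["lbm.coll_A"]],
                   coll_a = leaves[["lbm.coll_a"]])
  h_node <- lbm_encode_ad(ad_const(stack(ppg_b)), lbm_pars, object$lbm, g1)
  bb_pars <- leaves[startsWith(names(leaves), "bb.")]
  names(bb_pars) <- sub("^bb\\.", "", names(bb_pars))
  tw <- list(sa = rep(sqrt(sched$alpha_bar[tb]), each = L),
             s1 = rep(sqrt(1 - sched$alpha_bar[tb]), each = L))
  out <- backbone_forward_ad(ad_const(stack(xt)), tb, h_node, bb_pars,
                             cfg, geoms, tw = tw)
  l_diff <- if (cfg$head_param == "x0") {
    # the x0-parameterized head trains on the clean-signal scale, which is
    # the inverse-SNR-weighted form of the noise-prediction loss:
    # ||eps - eps_hat||^2 * (1-ab)/ab == ||x0 - x0_hat||^2
    ad_mse(out$x0_hat, ad_const(stack(x0_b)))
  } else {
    # bounded inverse-SNR weights on the noise residual
    wts <- pmax(pmin((1 - sched$alpha_bar[tb]) / sched$alpha_bar[tb],
                     object$snr_cap %||% 5), 1)
    wrow <- ad_const(rep(wts / mean(wts), each = L))
    dres <- ad_sub(out$eps_hat, ad_const(stack(eps)))
    ad_mean(ad_mul(ad_mul(dres, dres), wrow))
  }
  l_reg <- ad_bce(out$r_hat, stack(mask_b))
  # physics term on the Tweedie estimate (identical to the head output
  # under the x0 parameterization)
  x0_hat <- out$x0_hat
  target <- ad_addbias(ad_matmul(
    if (object$phys_target_detach) ad_const(vl(h_node)) else h_node,
    leaves[["proj_W"]]), leaves[["proj_b"]])
  l_phys <- ad_mse(ad_tdiff(x0_hat, g1), target)
  total <- ad_add(ad_add(ad_smul(l_diff, w$lambda_diff),
                         ad_smul(l_reg, w$lambda_reg)),
                  ad_smul(l_phys, w$lambda_phys))
  list(diff = l_diff, reg = l_reg, phys = l_phys, total = total)
}

## ---- Adam optimizer ----

.adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st
}

.adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- st$b1 * st$m[[nm]] + (1 - st$b1) * g
    st$v[[nm]] <- st$b2 * st$v[[nm]] + (1 - st$b2) * g * g
    params[[nm]] <- params[[nm]] -
      st$lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + st$eps)
  }
  params
}

## ---- inference ----

# parameters used at inference: exponential moving average if trained
.infer_params <- function(object, use_ema = TRUE) {
  if (use_ema && !is.null(object$ema) && object$trained_steps > 0L)
    object$ema else object$params
}

#' Encode PPG windows into hemodynamic features with a fitted model
#'
#' @param object A `"physdiff"` object.
#' @param ppg L x B matrix (or length-L vector) of normalized PPG windows.
#' @param use_ema Use the exponential moving average of the parameters
#'   (the default for all inference).
#' @return A `(B*L)` x 2 matrix of stacked `[rho, rho_u]` features.
#' @export
physdiff_encode <- function(object, ppg, use_ema = TRUE) {
  ppg <- as_mat(ppg)
  p <- .infer_params(object, use_ema)
  pars <- list(lift_W = as.numeric(p[["lbm.lift_W"]]),
               lift_b = as.numeric(p[["lbm.lift_b"]]),
               coll_A = p[["lbm.coll_A"]],
               coll_a = as.numeric(p[["lbm.coll_a"]]))
  do.call(rbind, lapply(seq_len(ncol(ppg)), function(j)
    lbm_encode(ppg[, j], pars, object$lbm)$h_phys))
}

#' Translate PPG windows into ECG windows
#'
#' Encodes each PPG window into hemodynamic features and draws an ECG
#' window by ancestral sampling from the reverse diffusion chain,
#' conditioned on those features.
#'
#' @param object A fitted `"physdiff"` object.
#' @param newdata A list of signal windows ([make_windows()]) or an L x B
#'   matrix of normalized PPG windows.
#' @param seed Integer seed for the sampler.
#' @param clip_x0 Clip the implied clean estimate to `[-1, 1]` during
#'   sampling (default `TRUE`).
#' @param use_ema Sample with the parameter moving average (default).
#' @param ... Unused.
#' @return An L x B matrix of generated ECG windows, aligned one-to-one
#'   with the inputs.
#' @export
predict.physdiff <- function(object, newdata, seed = 1L, clip_x0 = TRUE,
                             use_ema = TRUE, ...) {
  ppg <- if (is.list(newdata) && !is.data.frame(newdata))
    vapply(newdata, `[[`, numeric(object$cfg$L), "ppg") else as_mat(newdata)
  stopifnot(nrow(ppg) == object$cfg$L)
  B <- ncol(ppg)
  h <- physdiff_encode(object, ppg, use_ema = use_ema)
  pars <- .infer_params(object, use_ema)
  bb <- pars[startsWith(names(pars), "bb.")]
  names(bb) <- sub("^bb\\.", "", names(bb))
  cfg <- object$cfg
  eps_model <- function(x, t)
    backbone_forward(x, rep(t, ncol(x)), h, bb, cfg,
                     sched = object$sched)$eps_hat
  ancestral_sample(eps_model, B, cfg$L, object$sched, seed = seed,
                   clip_x0 = clip_x0)
}

#' Predicted QRS-region probability mask for PPG/ECG window pairs
#'
#' Runs the backbone once at the final (least noisy) timestep on the true
#' ECG to obtain the topology head's mask probabilities.
#'
#' @param object A fitted `"physdiff"` object.
#' @param windows List of signal windows.
#' @param use_ema Use the parameter moving average (default).
#' @return An L x B matrix of probabilities in `(0, 1)`.
#' @export
physdiff_mask <- function(object, windows, use_ema = TRUE) {
  L <- object$cfg$L
  ppg <- vapply(windows, `[[`, numeric(L), "ppg")
  ecg <- vapply(windows, `[[`, numeric(L), "ecg")
  h <- physdiff_encode(object, ppg, use_ema = use_ema)
  pars <- .infer_params(object, use_ema)
  bb <- pars[startsWith(names(pars), "bb.")]
  names(bb) <- sub("^bb\\.", "", names(bb))
  backbone_forward(ecg, rep(1L, ncol(ecg)), h, bb, object$cfg,
                   sched = object$sched)$r_hat
}
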