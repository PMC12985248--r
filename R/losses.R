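# Composite physics-informed training objective: noise-prediction MSE,
# QRS-mask binary cross-entropy, and the Tweedie-projected hemodynamic
# consistency term.

#' Loss weights
#'
#' @param lambda_diff,lambda_reg,lambda_phys Non-negative weights of the
#'   denoising, QRS-segmentation and physics-consistency terms.
#' @return An object of class `"loss_weights"`.
#' @export
loss_weights <- function(lambda_diff = 1, lambda_reg = 1,
                         lambda_phys = 0.1) {
  stopifnot(lambda_diff >= 0, lambda_reg >= 0, lambda_phys >= 0)
  structure(list(lambda_diff = lambda_diff, lambda_reg = lambda_reg,
                 lambda_phys = lambda_phys), class = "loss_weights")
}

#' Denoising loss: mean squared error on the predicted noise
#'
#' @param eps True injected noise.
#' @param eps_hat Predicted noise (same shape).
#' @return Non-negative scalar, mean over all elements.
#' @export
loss_diff <- function(eps, eps_hat) {
  stopifnot(length(eps) == length(eps_hat))
  mean((eps - eps_hat)^2)
}

#' QRS-region segmentation loss: mean binary cross-entropy
#'
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param r Binary ground-truth mask.
#' @param r_hat Predicted probabilities in `(0, 1)`.
#' @return Non-negative scalar.
#' @export
loss_reg <- function(r, r_hat) {
  stopifnot(length(r) == length(r_hat), all(r %in% c(0, 1)))
  p <- pmin(pmax(r_hat, 1e-7), 1 - 1e-7)
  -mean(r * log(p) + (1 - r) * log1p(-p))
}

# temporal derivative of a vector: central differences, one-sided at edges
temporal_derivative <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d
}

#' Hemodynamic consistency loss
#'
#' Mean squared error between the temporal derivative of the Tweedie
#' estimate and a learnable per-site linear projection of `h_phys`
#' (density and momentum channels mapped to one channel).
#'
#' @param x0_hat Length-L Tweedie estimate of the clean ECG.
#' @param h_phys L x 2 hemodynamic feature matrix.
#' @param proj_W Length-2 (or 2 x 1) projection weights.
#' @param proj_b Scalar projection bias.
#' @return Non-negative scalar.
#' @export
loss_phys <- function(x0_hat, h_phys, proj_W, proj_b = 0) {
  stopifnot(nrow(as_mat(h_phys)) == length(x0_hat))
  target <- as.numeric(as_mat(h_phys) %*% as_mat(proj_W)) + proj_b
  mean((temporal_derivative(x0_hat) - target)^2)
}

#' Weighted total loss
#'
#' @param components Named list or vector with elements `diff`, `reg`,
#'   `phys`.
#' @param weights A [loss_weights()].
#' @return `lambda_diff * L_diff + lambda_reg * L_reg +
#'   lambda_phys * L_phys`.
#' @export
loss_total <- function(components, weights = loss_weights()) {
  weights$lambda_diff * components[["diff"]] +
    weights$lambda_reg * components[["reg"]] +
    weights$lambda_phys * components[["phys"]]
}
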