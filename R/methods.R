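# S3 methods for the "physdiff" fit object.

#' @export
print.physdiff <- function(x, ...) {
  cat("Physics-aware PPG-to-ECG diffusion model\n")
  cat(sprintf("  window length L: %d   diffusion steps T: %d\n",
              x$cfg$L, x$sched$T))
  cat(sprintf("  backbone: depth %d, base width %d, attention d_k %d\n",
              x$cfg$n_scales, x$cfg$base_width, x$cfg$attention_dim))
  cat(sprintf("  LBM encoder: D1Q%d, K = %d collide-stream steps, %s projection\n",
              x$lbm$Q, x$lbm$n_steps, x$lbm$projection))
  cat(sprintf("  trained steps: %d on %d windows\n",
              x$trained_steps, x$n_windows))
  if (nrow(x$history) > 0L) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: L_diff %.4f  L_reg %.4f  L_phys %.4f\n",
                last$diff, last$reg, last$phys))
  }
  invisible(x)
}

#' @export
summary.physdiff <- function(object, ...) {
  np <- sum(vapply(object$params, length, 1L))
  s <- list(n_params = np, trained_steps = object$trained_steps,
            cfg = object$cfg, lbm = object$lbm,
            weights = object$weights, history = object$history)
  class(s) <- "summary.physdiff"
  s
}

#' @export
print.summary.physdiff <- function(x, ...) {
  cat(sprintf("physdiff model: %d parameters, %d training steps\n",
              x$n_params, x$trained_steps))
  cat(sprintf("loss weights: diff %.3g  reg %.3g  phys %.3g\n",
              x$weights$lambda_diff, x$weights$lambda_reg,
              x$weights$lambda_phys))
  if (nrow(x$history) > 0L) {
    h <- x$history
    k <- max(1L, nrow(h) - 49L)
    cat(sprintf("smoothed final L_diff (last %d steps): %.4f (first: %.4f)\n",
                nrow(h) - k + 1L, mean(h$diff[k:nrow(h)]), h$diff[1L]))
  }
  invisible(x)
}

#' @export
coef.physdiff <- function(object, ...) object$params

#' @export
plot.physdiff <- function(x, ...) {
  if (nrow(x$history) == 0L) {
    warning("no training history to plot")
    return(invisible(x))
  }
  h <- x$history
  graphics::matplot(h$step, cbind(h$diff, h$reg, h$phys), type = "l",
                    lty = 1, col = c("black", "steelblue", "firebrick"),
                    xlab = "step", ylab = "loss",
                    main = "training losses", ...)
  graphics::legend("topright", c("L_diff", "L_reg", "L_phys"), lty = 1,
                   col = c("black", "steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Draw ECG windows from the fitted conditional model
#'
#' @param object A fitted `"physdiff"` object.
#' @param nsim Number of samples per PPG window.
#' @param seed Integer seed.
#' @param newdata Windows or PPG matrix to condition on (required).
#' @param ... Passed to [predict.physdiff()].
#' @return A list of `nsim` L x B matrices.
#' @export
simulate.physdiff <- function(object, nsim = 1, seed = 1L, newdata, ...) {
  lapply(seq_len(nsim), function(i)
    predict(object, newdata, seed = seed + i - 1L, ...))
}

#' Reconstruction residuals on paired windows
#'
#' @param object A fitted `"physdiff"` object.
#' @param windows Paired signal windows with both `ppg` and `ecg`.
#' @param seed Sampler seed.
#' @param ... Unused.
#' @return An L x B matrix `true ECG - generated ECG`.
#' @export
residuals.physdiff <- function(object, windows, seed = 1L, ...) {
  ecg <- vapply(windows, `[[`, numeric(object$cfg$L), "ecg")
  ecg - predict(object, windows, seed = seed)
}
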