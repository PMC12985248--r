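# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Values are numeric matrices; a node is an environment holding the value,
# an accumulated gradient, and a backward closure that scatters the node's
# gradient into its parents.  A tape (creation-ordered list of nodes) is
# replayed in reverse by ad_backward().  When recording is off the same ops
# run as plain forward computations (used during sampling).
#
# Batched sequences use a "stacked rows" layout: a batch of B sequences of
# length L with C channels is a (B*L) x C matrix, batch-major (rows
# 1..L are element 1).  Structural ops (convolution gather, pooling,
# circular shifts) take precomputed index sets from ad_geom().

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$n <- 0L
.ad$recording <- FALSE

ad_begin <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$n <- 0L
  .ad$recording <- TRUE
  invisible(NULL)
}

ad_end <- function() {
  .ad$tape <- NULL
  .ad$n <- 0L
  .ad$recording <- FALSE
  invisible(NULL)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

ad_node <- function(val, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- if (.ad$recording) bw else NULL
  nd$id <- 0L
  class(nd) <- "ad_node"
  if (.ad$recording) {
    .ad$n <- .ad$n + 1L
    if (.ad$n > length(.ad$tape)) length(.ad$tape) <- 2L * length(.ad$tape)
    .ad$tape[[.ad$n]] <- nd
    nd$id <- .ad$n
  }
  nd
}

#' @export
print.ad_node <- function(x, ...) {
  cat("<ad_node ", paste(dim(x$val), collapse = "x"), ">\n", sep = "")
  invisible(x)
}

ad_leaf <- function(val) ad_node(as_mat(val))
ad_const <- function(val) {
  nd <- ad_node(as_mat(val))
  nd$const <- TRUE
  nd
}

vl <- function(x) if (inherits(x, "ad_node")) x$val else as_mat(x)

.acc <- function(nd, g) {
  if (isTRUE(nd$const)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# accumulate g's rows into nd$grad rows `idx`; set unique = TRUE when the
# caller guarantees idx has no duplicates (skips the rowsum aggregation)
.acc_rows <- function(nd, idx, g, unique = FALSE) {
  if (isTRUE(nd$const)) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- matrix(0, nrow(nd$val), ncol(nd$val))
  if (!unique && anyDuplicated(idx)) {
    s <- rowsum(g, idx)
    rows <- as.integer(rownames(s))
    nd$grad[rows, ] <- nd$grad[rows, , drop = FALSE] + s
  } else {
    nd$grad[idx, ] <- nd$grad[idx, , drop = FALSE] + g
  }
  invisible(NULL)
}

ad_backward <- function(loss) {
  stopifnot(.ad$recording, length(vl(loss)) == 1L)
  loss$grad <- matrix(1, 1, 1)
  for (i in seq(loss$id, 1L)) {
    nd <- .ad$tape[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

## ---- elementwise and linear algebra ----

ad_add <- function(a, b) {
  A <- vl(a); B <- vl(b)
  ad_node(A + B, function(g) { .acc(a, g); .acc(b, g) })
}

ad_sub <- function(a, b) {
  A <- vl(a); B <- vl(b)
  ad_node(A - B, function(g) { .acc(a, g); .acc(b, -g) })
}

ad_mul <- function(a, b) {
  A <- vl(a); B <- vl(b)
  ad_node(A * B, function(g) { .acc(a, g * B); .acc(b, g * A) })
}

# multiply by a plain scalar
ad_smul <- function(a, s) {
  A <- vl(a)
  ad_node(A * s, function(g) .acc(a, g * s))
}

ad_matmul <- function(a, b) {
  A <- vl(a); B <- vl(b)
  ad_node(A %*% B, function(g) {
    .acc(a, g %*% t(B))
    .acc(b, crossprod(A, g))
  })
}

ad_transpose <- function(a) {
  ad_node(t(vl(a)), function(g) .acc(a, t(g)))
}

# add a length-C bias vector to every row of a (B*L) x C matrix
ad_addbias <- function(a, b) {
  A <- vl(a); bv <- as.numeric(vl(b))
  ad_node(A + rep(bv, each = nrow(A)),
          function(g) { .acc(a, g); .acc(b, as_mat(colSums(g))) })
}

# add per-batch-element row vectors E (B x C) to blocks of a ((B*L) x C)
ad_addrows <- function(a, e, blockid) {
  A <- vl(a); E <- vl(e)
  ad_node(A + E[blockid, , drop = FALSE], function(g) {
    .acc(a, g)
    .acc(e, rowsum(g, blockid))
  })
}

## ---- activations ----

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
.sigmoid <- function(x) 1 / (1 + exp(-x))

ad_softplus <- function(a) {
  A <- vl(a)
  ad_node(.softplus(A), function(g) .acc(a, g * .sigmoid(A)))
}

ad_sigmoid <- function(a) {
  A <- vl(a); S <- .sigmoid(A)
  ad_node(S, function(g) .acc(a, g * S * (1 - S)))
}

ad_silu <- function(a) {
  A <- vl(a); S <- .sigmoid(A)
  ad_node(A * S, function(g) .acc(a, g * S * (1 + A * (1 - S))))
}

ad_softmax_rows <- function(a) {
  A <- vl(a)
  m <- apply(A, 1L, max)
  E <- exp(A - m)
  S <- E / rowSums(E)
  ad_node(S, function(g) .acc(a, S * (g - rowSums(g * S))))
}

## ---- reductions and losses ----

ad_mean <- function(a) {
  A <- vl(a); n <- length(A)
  ad_node(matrix(mean(A), 1, 1),
          function(g) .acc(a, matrix(g[1] / n, nrow(A), ncol(A))))
}

ad_mse <- function(a, target) {
  A <- vl(a); Tm <- vl(target); n <- length(A)
  ad_node(matrix(mean((A - Tm)^2), 1, 1), function(g) {
    d <- g[1] * 2 * (A - Tm) / n
    .acc(a, d)
    if (inherits(target, "ad_node")) .acc(target, -d)
  })
}

# mean binary cross-entropy of probabilities vs a {0,1} target,
# probabilities clamped to [eps, 1 - eps]
ad_bce <- function(a, target, eps = 1e-7) {
  A <- vl(a); Tm <- vl(target); n <- length(A)
  P <- pmin(pmax(A, eps), 1 - eps)
  val <- -mean(Tm * log(P) + (1 - Tm) * log1p(-P))
  ad_node(matrix(val, 1, 1), function(g) {
    d <- g[1] * (-(Tm / P) + (1 - Tm) / (1 - P)) / n
    d[A < eps | A > 1 - eps] <- 0
    .acc(a, d)
  })
}

## ---- structural ops on stacked-row batches ----

# Precomputed index structures for a fixed (L, B) level.
ad_geom <- function(L, B, K = 3L) {
  stopifnot(K %% 2L == 1L)
  half <- (K - 1L) %/% 2L
  n <- L * B
  blockid <- rep(seq_len(B), each = L)
  tpos <- rep(seq_len(L), times = B)
  # conv gather: index into rbind(0, X); 1 = zero pad row
  idx <- matrix(1L, n, K)
  for (k in seq_len(K)) {
    off <- k - 1L - half
    u <- tpos + off
    ok <- u >= 1L & u <= L
    idx[ok, k] <- (blockid[ok] - 1L) * L + u[ok] + 1L
  }
  # average pooling by 2 within each block
  pool <- NULL
  if (L %% 2L == 0L) {
    t1 <- rep(seq(1L, L, by = 2L), times = B) +
      rep((seq_len(B) - 1L) * L, each = L %/% 2L)
    pool <- list(i1 = t1, i2 = t1 + 1L)
  }
  list(L = L, B = B, K = K, n = n, blockid = blockid, tpos = tpos,
       conv_idx = idx, pool = pool)
}

# 1D convolution (kernel K, stride 1, zero padding, "same" length).
# x: (B*L) x Cin; W: (K*Cin) x Cout with taps stacked blockwise; b: Cout.
ad_conv1d <- function(x, W, b, geom) {
  X <- vl(x); Wm <- vl(W)
  K <- geom$K; Cin <- ncol(X)
  Xp <- rbind(matrix(0, 1L, Cin), X)
  Xc <- matrix(0, geom$n, K * Cin)
  for (k in seq_len(K))
    Xc[, ((k - 1L) * Cin + 1L):(k * Cin)] <- Xp[geom$conv_idx[, k], , drop = FALSE]
  bv <- as.numeric(vl(b))
  Y <- Xc %*% Wm + rep(bv, each = geom$n)
  ad_node(Y, function(g) {
    .acc(b, as_mat(colSums(g)))
    .acc(W, crossprod(Xc, g))
    dXc <- g %*% t(Wm)
    dX <- matrix(0, nrow(X), Cin)
    for (k in seq_len(K)) {
      rows <- geom$conv_idx[, k]
      live <- rows > 1L
      tgt <- rows[live] - 1L
      dX[tgt, ] <- dX[tgt, , drop = FALSE] +
        dXc[live, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
    }
    .acc(x, dX)
  })
}

ad_avgpool2 <- function(x, geom) {
  X <- vl(x); p <- geom$pool
  ad_node((X[p$i1, , drop = FALSE] + X[p$i2, , drop = FALSE]) / 2,
          function(g) {
            gh <- g / 2
            .acc_rows(x, p$i1, gh, unique = TRUE)
            .acc_rows(x, p$i2, gh, unique = TRUE)
          })
}

# nearest-neighbour upsampling by 2 (input level geometry `geom`)
ad_upsample2 <- function(x, geom) {
  X <- vl(x)
  n <- geom$n
  # stacked-row layout: duplicate each row in place within its block
  src <- as.integer(rep((seq_len(geom$B) - 1L) * geom$L, each = 2L * geom$L)) +
    rep(rep(seq_len(geom$L), each = 2L), times = geom$B)
  ad_node(X[src, , drop = FALSE], function(g) {
    odd <- seq(1L, 2L * n, by = 2L)
    .acc(x, g[odd, , drop = FALSE] + g[odd + 1L, , drop = FALSE])
  })
}

# circular shift of each channel within each block; shifts[c] = advection step
ad_shift_circ <- function(x, shifts, geom) {
  X <- vl(x)
  L <- geom$L
  Y <- X
  perms <- vector("list", ncol(X))
  for (c in seq_len(ncol(X))) {
    s <- shifts[c] %% L
    if (s == 0) next
    # y[t] = x[t - s]  (delta advected forward by s)
    src_local <- ((seq_len(L) - 1L - s) %% L) + 1L
    perm <- as.integer(rep((seq_len(geom$B) - 1L) * L, each = L)) +
      rep(src_local, times = geom$B)
    perms[[c]] <- perm
    Y[, c] <- X[perm, c]
  }
  ad_node(Y, function(g) {
    d <- g
    for (c in seq_len(ncol(g))) {
      if (!is.null(perms[[c]])) {
        d[, c] <- 0
        d[perms[[c]], c] <- g[, c]
      }
    }
    .acc(x, d)
  })
}

# group normalization with per-channel affine parameters.
# Statistics are over (time x channels-in-group) within each batch element.
ad_groupnorm <- function(x, gamma, beta, groups, geom, eps = 1e-5) {
  X <- vl(x)
  C <- ncol(X)
  stopifnot(C %% groups == 0L)
  cg <- C %/% groups            # channels per group
  colgrp <- rep(seq_len(groups), each = cg)
  Gm <- matrix(0, C, groups); Gm[cbind(seq_len(C), colgrp)] <- 1
  L <- geom$L; blockid <- geom$blockid
  ne <- L * cg                  # elements per (block, group)
  bs <- rowsum(X, blockid)      # B x C sums
  mu <- (bs %*% Gm) / ne        # B x G
  bss <- rowsum(X * X, blockid)
  ex2 <- (bss %*% Gm) / ne
  v <- pmax(ex2 - mu^2, 0)
  inv <- 1 / sqrt(v + eps)      # B x G
  mu_big <- mu[blockid, colgrp, drop = FALSE]
  inv_big <- inv[blockid, colgrp, drop = FALSE]
  xhat <- (X - mu_big) * inv_big
  gv <- as.numeric(vl(gamma))
  Y <- xhat * rep(gv, each = nrow(X)) + rep(as.numeric(vl(beta)), each = nrow(X))
  ad_node(Y, function(g) {
    .acc(beta, as_mat(colSums(g)))
    .acc(gamma, as_mat(colSums(g * xhat)))
    dxh <- g * rep(gv, each = nrow(g))
    m1 <- ((rowsum(dxh, blockid) %*% Gm) / ne)[blockid, colgrp, drop = FALSE]
    m2 <- ((rowsum(dxh * xhat, blockid) %*% Gm) / ne)[blockid, colgrp, drop = FALSE]
    .acc(x, inv_big * (dxh - m1 - xhat * m2))
  })
}

# row subsetting (contiguous or general); backward scatters
ad_rows <- function(x, idx) {
  X <- vl(x)
  ad_node(X[idx, , drop = FALSE], function(g) .acc_rows(x, idx, g))
}

ad_rbind <- function(nodes) {
  vals <- lapply(nodes, vl)
  nr <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nr)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ad_node(do.call(rbind, vals), function(g) {
    for (i in seq_along(nodes))
      .acc(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
  })
}

ad_cbind <- function(a, b) {
  A <- vl(a); B <- vl(b)
  ca <- ncol(A)
  ad_node(cbind(A, B), function(g) {
    .acc(a, g[, seq_len(ca), drop = FALSE])
    .acc(b, g[, (ca + 1L):ncol(g), drop = FALSE])
  })
}

# add a learnable relative-position bias to square attention logits:
# out[i, j] = logits[i, j] + rel[j - i + Lp]
ad_relbias <- function(logits, rel, Lp) {
  Lg <- vl(logits)
  idx <- outer(seq_len(Lp), seq_len(Lp), function(i, j) j - i + Lp)
  rv <- as.numeric(vl(rel))
  ad_node(Lg + matrix(rv[idx], Lp, Lp), function(g) {
    .acc(logits, g)
    s <- rowsum(as.numeric(g), as.integer(idx))
    d <- matrix(0, length(rv), 1L)
    d[as.integer(rownames(s)), 1L] <- s
    .acc(rel, d)
  })
}

# temporal derivative: central differences inside, one-sided at block edges
ad_tdiff <- function(x, geom) {
  X <- vl(x)
  L <- geom$L; B <- geom$B
  base <- rep((seq_len(B) - 1L) * L, each = L)
  tpos <- rep(seq_len(L), times = B)
  inx <- base + pmin(tpos + 1L, L)
  ipv <- base + pmax(tpos - 1L, 1L)
  w <- rep(0.5, geom$n)
  w[tpos == 1L | tpos == L] <- 1
  D <- w * (X[inx, , drop = FALSE] - X[ipv, , drop = FALSE])
  ad_node(D, function(g) {
    gw <- g * w
    .acc_rows(x, inx, gw)
    .acc_rows(x, ipv, -gw)
  })
}
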