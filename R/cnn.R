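# Lightweight 1D convolutional network, implemented directly on base-R
# matrix algebra. Convolutions run as im2col matrix products; the batch
# dimension is vectorized throughout. The architecture is fixed by contract:
# two [conv -> ReLU -> max-pool] blocks followed by five dense layers with
# ReLU between (none after the last), producing one logit per gesture class.

#' Model architecture configuration
#'
#' @param n_channels Input channel count.
#' @param n_classes Number of gesture classes (>= 1); sets the final dense
#'   width.
#' @param window_len Input window length in samples (default 32).
#' @param conv_blocks List of exactly two blocks, each
#'   `c(filters, kernel, pool)` (defaults `c(32, 3, 2)` then `c(64, 3, 2)`).
#' @param dense_widths Widths of the five dense layers; the last must equal
#'   `n_classes` (default `c(256, 128, 64, 32, n_classes)`).
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_channels, n_classes, window_len = 32L,
                         conv_blocks = list(c(32L, 3L, 2L), c(64L, 3L, 2L)),
                         dense_widths = NULL) {
  if (is.null(dense_widths)) dense_widths <- c(256L, 128L, 64L, 32L, n_classes)
  if (length(conv_blocks) != 2) stop("exactly 2 convolutional blocks required")
  if (length(dense_widths) != 5) stop("exactly 5 dense layers required")
  if (dense_widths[5] != n_classes) {
    stop("final dense width must equal n_classes")
  }
  if (n_classes < 1 || any(dense_widths < 1)) stop("all widths must be >= 1")
  # length surviving both conv (valid) + pool stages
  len <- window_len
  for (b in conv_blocks) {
    len <- len - b[2] + 1
    if (len < 1) break
    len <- len %/% b[3]
  }
  if (len < 1) {
    min_len <- min_window_len(conv_blocks)
    stop("window_len ", window_len, " too short for the configured kernels/",
         "pools; minimum is ", min_len)
  }
  structure(
    list(n_channels = as.integer(n_channels),
         window_len = as.integer(window_len),
         n_classes = as.integer(n_classes),
         conv_blocks = lapply(conv_blocks, as.integer),
         dense_widths = as.integer(dense_widths),
         flat_dim = as.integer(len * conv_blocks[[2]][1])),
    class = "model_config"
  )
}

min_window_len <- function(conv_blocks) {
  # smallest L with >= 1 output position after both blocks, found by scan
  for (L in 1:256) {
    len <- L
    ok <- TRUE
    for (b in conv_blocks) {
      len <- len - b[2] + 1
      if (len < 1) { ok <- FALSE; break }
      len <- len %/% b[3]
      if (len < 1) { ok <- FALSE; break }
    }
    if (ok) return(L)
  }
  stop("no feasible window length up to 256")
}

#' Initialize a gesture classification model
#'
#' Allocates He-initialized weights for the configured architecture.
#' Initialization is deterministic under `seed`.
#'
#' @param cfg A `model_config`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cnn_model` holding `cfg` and a named
#'   parameter list.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(derive_seed(seed, 303L), {
    p <- list()
    in_ch <- cfg$n_channels
    for (i in 1:2) {
      blk <- cfg$conv_blocks[[i]]
      fan_in <- in_ch * blk[2]
      p[[paste0("Wc", i)]] <- matrix(
        stats::rnorm(fan_in * blk[1], 0, sqrt(2 / fan_in)), fan_in, blk[1])
      p[[paste0("bc", i)]] <- numeric(blk[1])
      in_ch <- blk[1]
    }
    d_in <- cfg$flat_dim
    for (j in 1:5) {
      d_out <- cfg$dense_widths[j]
      p[[paste0("Wd", j)]] <- matrix(
        stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out)
      p[[paste0("bd", j)]] <- numeric(d_out)
      d_in <- d_out
    }
    structure(list(cfg = cfg, params = p), class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<cnn_model> %d ch x %d samples -> %d classes; 2 conv + 5 dense, %d parameters\n",
    x$cfg$n_channels, x$cfg$window_len, x$cfg$n_classes, np))
  invisible(x)
}

# im2col over the time axis. x: array B x C x L (C = channels for block 1,
# filters thereafter, stored as B x L x C from block 2 on — `time_first`
# says which layout). Returns (B*Lout) x (C*k) with row index b + (t-1)*B.
im2col <- function(x, k, time_first) {
  d <- dim(x)
  B <- d[1]
  if (time_first) { L <- d[2]; C <- d[3] } else { C <- d[2]; L <- d[3] }
  Lout <- L - k + 1
  m <- matrix(0, B * Lout, C * k)
  for (c in seq_len(C)) {
    for (kk in seq_len(k)) {
      sl <- if (time_first) x[, kk:(kk + Lout - 1), c] else x[, c, kk:(kk + Lout - 1)]
      m[, (c - 1) * k + kk] <- as.vector(sl)
    }
  }
  m
}

# Forward pass. X: array B x C x L. Returns logits (B x n_classes); with
# cache = TRUE also every intermediate needed for the backward pass.
cnn_forward <- function(model, X, cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  B <- dim(X)[1]
  st <- list(X = X)
  a <- X; time_first <- FALSE
  for (i in 1:2) {
    blk <- cfg$conv_blocks[[i]]
    k <- blk[2]; pool <- blk[3]; f <- blk[1]
    M <- im2col(a, k, time_first)
    Z <- sweep(M %*% p[[paste0("Wc", i)]], 2, p[[paste0("bc", i)]], `+`)
    A <- Z * (Z > 0)
    Lout <- nrow(M) / B
    dim(A) <- c(B, Lout, f)
    Lp <- Lout %/% pool
    base <- seq.int(1L, by = pool, length.out = Lp)
    P <- A[, base, , drop = FALSE]
    amax <- array(1L, dim = dim(P)) # offset winning the max; first wins ties
    if (pool > 1) {
      for (o in 2:pool) {
        cand <- A[, base + (o - 1L), , drop = FALSE]
        upd <- cand > P
        P[upd] <- cand[upd]
        amax[upd] <- o
      }
    }
    if (cache) {
      st[[paste0("M", i)]] <- M
      st[[paste0("Zpos", i)]] <- Z > 0
      st[[paste0("amax", i)]] <- amax
      st[[paste0("Lout", i)]] <- Lout
      st[[paste0("Lp", i)]] <- Lp
    }
    a <- P
    time_first <- TRUE
  }
  H <- a
  dim(H) <- c(B, cfg$flat_dim)
  for (j in 1:5) {
    Z <- sweep(H %*% p[[paste0("Wd", j)]], 2, p[[paste0("bd", j)]], `+`)
    if (cache) {
      st[[paste0("Hin", j)]] <- H
      st[[paste0("Zdpos", j)]] <- Z > 0
    }
    H <- if (j < 5) Z * (Z > 0) else Z
  }
  if (cache) list(logits = H, cache = st) else H
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy loss and parameter gradients for integer class labels
# y (0-based). Returns list(loss, grads) with grads named like params.
cnn_loss_grads <- function(model, X, y) {
  cfg <- model$cfg; p <- model$params
  fw <- cnn_forward(model, X, cache = TRUE)
  st <- fw$cache
  B <- dim(X)[1]
  P <- softmax_rows(fw$logits)
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  g <- list()
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  dZ <- dZ / B
  for (j in 5:1) {
    H <- st[[paste0("Hin", j)]]
    g[[paste0("Wd", j)]] <- crossprod(H, dZ)
    g[[paste0("bd", j)]] <- colSums(dZ)
    dH <- tcrossprod(dZ, p[[paste0("Wd", j)]])
    if (j > 1) dZ <- dH * st[[paste0("Zdpos", j - 1)]]
  }
  # dH: gradient w.r.t. the flattened conv output
  dP <- dH
  dim(dP) <- c(B, st$Lp2, cfg$conv_blocks[[2]][1])
  for (i in 2:1) {
    blk <- cfg$conv_blocks[[i]]
    k <- blk[2]; pool <- blk[3]; f <- blk[1]
    Lout <- st[[paste0("Lout", i)]]
    Lp <- st[[paste0("Lp", i)]]
    amax <- st[[paste0("amax", i)]]
    base <- seq.int(1L, by = pool, length.out = Lp)
    dA <- array(0, dim = c(B, Lout, f))
    for (o in seq_len(pool)) {
      sel <- amax == o
      slab <- dA[, base + (o - 1L), , drop = FALSE]
      slab[sel] <- slab[sel] + dP[sel]
      dA[, base + (o - 1L), ] <- slab
    }
    dim(dA) <- c(B * Lout, f)
    dZc <- dA * st[[paste0("Zpos", i)]]
    g[[paste0("Wc", i)]] <- crossprod(st[[paste0("M", i)]], dZc)
    g[[paste0("bc", i)]] <- colSums(dZc)
    if (i == 2) {
      # propagate into block 1's pooled output (layout B x Lp1 x F1)
      dM <- tcrossprod(dZc, p$Wc2)
      f_in <- cfg$conv_blocks[[1]][1]
      L2 <- st$Lout2
      dP <- array(0, dim = c(B, st$Lp1, f_in))
      for (c in seq_len(f_in)) {
        for (kk in seq_len(k)) {
          dP[, kk:(kk + L2 - 1), c] <- dP[, kk:(kk + L2 - 1), c] +
            matrix(dM[, (c - 1) * k + kk], B, L2)
        }
      }
    }
  }
  list(loss = loss, grads = g)
}

# One Adam update in place; state carries first/second moments and step t.
adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.001,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
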