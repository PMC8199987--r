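# Minimal 3D convolutional network engine.
#
# Convolutions are evaluated as one BLAS gemm per layer via im2col (compiled
# in src/ops.cpp), which is what makes desk-scale 3D training practical on a
# single CPU. Everything is functional: forward passes return caches, the
# backward passes return gradient lists shaped like the parameter lists, and
# Adam produces a new parameter list. All stochastic choices (init, epoch
# shuffling) are drawn under seeds supplied by the caller, so runs are
# bit-reproducible.

# ---- primitive layers -------------------------------------------------------

conv_fwd <- function(x, W, b, k) {
  list(y = conv3_fwd(x, W, b), x = x, xdim = as.integer(dim(x)))
}

conv_bwd <- function(cache, W, k, gy) {
  gw <- conv3_bwd_w(cache$x, gy, k)
  list(gW = gw$gW, gb = gw$gb, gx = conv3_bwd_x(gy, W, cache$xdim))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- c(a, b)                       # channel-last column-major: channels append
  dim(out) <- c(da[1:3], da[4] + db[4])
  out
}

split_channels <- function(g, c1) {
  d <- dim(g)
  n <- prod(d[1:3])
  g1 <- g[seq_len(n * c1)]
  g2 <- g[-seq_len(n * c1)]
  dim(g1) <- c(d[1:3], c1)
  dim(g2) <- c(d[1:3], d[4] - c1)
  list(g1, g2)
}

he_init <- function(k, cin, cout, scale = 2) {
  W <- array(rnorm(k^3 * cin * cout, sd = sqrt(scale / (k^3 * cin))),
             c(k, k, k, cin, cout))
  list(W = W, b = rep(0, cout))
}

softmax4 <- function(logits) {
  d <- dim(logits)
  C <- d[4]
  m <- logits[, , , 1]
  if (C > 1) for (cc in 2:C) m <- pmax(m, logits[, , , cc])
  e <- exp(logits - as.vector(m))
  s <- e[, , , 1]
  if (C > 1) for (cc in 2:C) s <- s + e[, , , cc]
  e / as.vector(s)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0), how = "list",
         classes = c("matrix", "numeric", "array"))
}

adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(p) && !is.null(names(p)) && all(c("W", "b") %in% names(p))) {
      rw <- upd(p$W, g$W, s$W); rb <- upd(p$b, g$b, s$b)
      list(p = list(W = rw$p, b = rb$p), s = list(W = rw$s, b = rb$s))
    } else if (is.list(p)) {
      res <- Map(walk, p, g, s)
      list(p = lapply(res, `[[`, "p"), s = lapply(res, `[[`, "s"))
    } else {
      upd(p, g, s)
    }
  }
  walk(params, grads, state)
}

adam_state_init <- function(params) {
  walk <- function(p) {
    if (is.list(p) && !is.null(names(p)) && all(c("W", "b") %in% names(p)))
      list(W = list(m = p$W * 0, v = p$W * 0), b = list(m = p$b * 0, v = p$b * 0))
    else if (is.list(p)) lapply(p, walk)
    else list(m = p * 0, v = p * 0)
  }
  walk(params)
}

# Sum of element counts over a nested parameter list.
count_params <- function(params) {
  s <- 0
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else s <<- s + length(p)
    invisible(NULL)
  }
  walk(params)
  s
}
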