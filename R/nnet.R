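# Internal neural-network math for the Q-function.
#
# Activations flow in "position-major" layout: a batch of B states, each a
# W x C channel map, is held as a (B*W) x C matrix whose row (w-1)*B + b is
# position w of sample b. 1D convolutions then become a sum over kernel taps
# of row-shifted matrix products, which keeps everything inside BLAS.

# batch x (W*C) position-interleaved matrix -> (B*W) x C
pos_major <- function(X, batch, ch, W) {
  arr <- array(X, dim = c(batch, ch, W))
  H <- aperm(arr, c(1, 3, 2))
  dim(H) <- c(batch * W, ch)
  H
}

# (B*W) x C -> batch x (W*C)
pos_flat <- function(H, batch, W, ch) {
  arr <- array(H, dim = c(batch, W, ch))
  X <- aperm(arr, c(1, 3, 2))
  dim(X) <- c(batch, ch * W)
  X
}

# shift rows so output position w reads input position w + o (zeros at ends)
row_shift <- function(H, o, batch) {
  if (o == 0) return(H)
  n <- nrow(H)
  s <- o * batch
  out <- matrix(0, n, ncol(H))
  if (s > 0) out[1:(n - s), ] <- H[(s + 1):n, , drop = FALSE]
  else out[(1 - s):n, ] <- H[1:(n + s), , drop = FALSE]
  out
}

conv_forward <- function(H, par, batch, taps) {
  k <- length(taps)
  if (par$type == "standard") {
    Y <- matrix(par$b, nrow(H), length(par$b), byrow = TRUE)
    for (ti in seq_len(k))
      Y <- Y + row_shift(H, taps[ti], batch) %*% par$Wt[[ti]]
    list(Y = Y, D = NULL)
  } else {
    D <- matrix(0, nrow(H), ncol(H))
    for (ti in seq_len(k))
      D <- D + row_shift(H, taps[ti], batch) %*% diag(par$Dw[ti, ], ncol(H))
    Y <- D %*% par$P + matrix(par$b, nrow(H), length(par$b), byrow = TRUE)
    list(Y = Y, D = D)
  }
}

conv_backward <- function(dY, H, fw, par, batch, taps) {
  k <- length(taps)
  if (par$type == "standard") {
    g <- list(Wt = vector("list", k), b = colSums(dY))
    dH <- matrix(0, nrow(H), ncol(H))
    for (ti in seq_len(k)) {
      Hs <- row_shift(H, taps[ti], batch)
      g$Wt[[ti]] <- crossprod(Hs, dY)
      dH <- dH + row_shift(dY %*% t(par$Wt[[ti]]), -taps[ti], batch)
    }
    list(grads = g, dH = dH)
  } else {
    dD <- dY %*% t(par$P)
    g <- list(Dw = matrix(0, k, ncol(H)), P = crossprod(fw$D, dY),
              b = colSums(dY))
    dH <- matrix(0, nrow(H), ncol(H))
    for (ti in seq_len(k)) {
      Hs <- row_shift(H, taps[ti], batch)
      g$Dw[ti, ] <- colSums(Hs * dD)
      dH <- dH + row_shift(dD %*% diag(par$Dw[ti, ], ncol(H)), -taps[ti], batch)
    }
    list(grads = g, dH = dH)
  }
}

# recursive map over numeric leaves of two parallel param structures;
# matched by name where available so bookkeeping fields (e.g. "type",
# absent from gradient structures) stay untouched
param_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
          else seq_along(a)
  out <- a
  for (k in keys) {
    if (is.numeric(a[[k]]) || is.list(a[[k]]))
      out[[k]] <- param_map2(a[[k]], b[[k]], f)
  }
  out
}

param_map1 <- function(a, f) {
  if (is.numeric(a)) return(f(a))
  out <- a
  for (nm in seq_along(a)) {
    if (is.numeric(a[[nm]]) || is.list(a[[nm]]))
      out[[nm]] <- param_map1(a[[nm]], f)
  }
  out
}

param_reduce <- function(a, f, acc = 0) {
  if (is.numeric(a)) return(f(acc, a))
  for (nm in seq_along(a)) {
    if (is.numeric(a[[nm]]) || is.list(a[[nm]]))
      acc <- param_reduce(a[[nm]], f, acc)
  }
  acc
}

# skip non-numeric bookkeeping fields ("type") during traversal:
# param_map* recurse only into numeric or list elements, so character
# fields pass through untouched.

net_forward <- function(net, X, want_cache = FALSE) {
  cfg <- net$config
  batch <- nrow(X)
  W <- cfg$window
  taps <- net$taps
  H <- pos_major(X, batch, 10L, W)
  cache <- if (want_cache) list(H_in = list(), fw = list(), X = X) else NULL
  for (bi in seq_along(net$params$conv)) {
    par <- net$params$conv[[bi]]
    fw <- conv_forward(H, par, batch, taps)
    Z <- fw$Y
    Z[Z < 0] <- 0
    if (want_cache) {
      cache$H_in[[bi]] <- H
      cache$fw[[bi]] <- fw
    }
    H <- Z
  }
  chL <- ncol(H)
  Fm <- pos_flat(H, batch, W, chL)
  pre <- Fm %*% net$params$dense$W +
    matrix(net$params$dense$b, batch, length(net$params$dense$b), byrow = TRUE)
  Hd <- pre; Hd[Hd < 0] <- 0
  V <- Hd %*% net$params$v$W + net$params$v$b
  A <- Hd %*% net$params$a$W +
    matrix(net$params$a$b, batch, 3L, byrow = TRUE)
  Q <- A - rowMeans(A) + as.vector(V)
  colnames(Q) <- ACTIONS
  if (want_cache) {
    cache$Fm <- Fm; cache$pre <- pre; cache$Hd <- Hd
    cache$chL <- chL; cache$batch <- batch
    list(Q = Q, V = V, A = A, cache = cache)
  } else list(Q = Q, V = V, A = A)
}

net_backward <- function(net, cache, dQ) {
  cfg <- net$config
  batch <- cache$batch
  W <- cfg$window
  taps <- net$taps
  dA <- dQ - rowMeans(dQ)
  dV <- rowSums(dQ)
  g <- list()
  g$v <- list(W = crossprod(cache$Hd, dV), b = sum(dV))
  g$a <- list(W = crossprod(cache$Hd, dA), b = colSums(dA))
  dHd <- dA %*% t(net$params$a$W) + outer(dV, as.vector(net$params$v$W))
  dpre <- dHd * (cache$pre > 0)
  g$dense <- list(W = crossprod(cache$Fm, dpre), b = colSums(dpre))
  dF <- dpre %*% t(net$params$dense$W)
  dH <- pos_major(dF, batch, cache$chL, W)
  g$conv <- vector("list", length(net$params$conv))
  for (bi in rev(seq_along(net$params$conv))) {
    par <- net$params$conv[[bi]]
    dY <- dH * (cache$fw[[bi]]$Y > 0)
    bk <- conv_backward(dY, cache$H_in[[bi]], cache$fw[[bi]], par, batch, taps)
    g$conv[[bi]] <- bk$grads
    dH <- bk$dH
  }
  g
}

adam_step <- function(net, grads, lr, clip_norm = 10) {
  sq <- param_reduce(grads, function(acc, x) acc + sum(x * x))
  gn <- sqrt(sq)
  if (is.finite(clip_norm) && gn > clip_norm) {
    sc <- clip_norm / gn
    grads <- param_map1(grads, function(x) x * sc)
  }
  net$opt$t <- net$opt$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- net$opt$t
  net$opt$m <- param_map2(net$opt$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  net$opt$v <- param_map2(net$opt$v, grads, function(v, g) b2 * v + (1 - b2) * g * g)
  corr <- lr * sqrt(1 - b2^t) / (1 - b1^t)
  upd <- param_map2(net$opt$m, net$opt$v,
                    function(m, v) corr * m / (sqrt(v) + eps))
  net$params <- param_map2(net$params, upd, function(p, u) p - u)
  net
}
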