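# Internal neural-network primitives for the four-head fusion regressor.
#
# Everything is dense double-precision linear algebra dispatched to BLAS.
# Layout conventions:
#   token matrices       n x L      (integer, 0 = padding)
#   activation arrays    n x L x C  (sample, position, channel)
#   dense activations    n x width
# Convolutions are "valid" (no implicit padding); the padding embedding row
# is identically zero and non-trainable, which makes conv outputs over pure
# padding constant per filter. Under max-over-time pooling this allows an
# exact shortcut: evaluate only positions whose receptive field can touch a
# real token, plus one pure-padding position, and the pooled output equals
# the full-length computation bit for bit (see the methods vignette).

relu <- function(x) x * (x > 0)

embed_tokens <- function(tokens, emb) {
  n <- nrow(tokens); L <- ncol(tokens); C <- ncol(emb)
  flat <- as.integer(tokens)
  X <- matrix(0, n * L, C)
  nz <- flat > 0L
  if (any(nz)) X[nz, ] <- emb[flat[nz], , drop = FALSE]
  dim(X) <- c(n, L, C)
  X
}

embed_backward <- function(tokens, dX, vocab_rows) {
  n <- dim(dX)[1]; L <- dim(dX)[2]; C <- dim(dX)[3]
  flat <- as.integer(tokens)
  dim(dX) <- c(n * L, C)
  nz <- flat > 0L
  demb <- matrix(0, vocab_rows, C)
  if (any(nz)) {
    g <- rowsum(dX[nz, , drop = FALSE], group = flat[nz])
    demb[as.integer(rownames(g)), ] <- g
  }
  demb
}

# In the (n, L, C) column-major layout the (sample, position) pair flattens
# position-major, so the kernel shift k selects the contiguous row block
# ((k-1)n + 1) : ((k-1+Lout)n) of the n*L x C matrix view — convolutions
# reduce to K dense gemms on row blocks with no 3-D indexing.
conv1d_forward <- function(X, W, b) {
  dms <- dim(X); n <- dms[1]; L <- dms[2]; Cin <- dms[3]
  K <- dim(W)[1]; Fo <- dim(W)[3]
  Lout <- L - K + 1L
  if (Lout < 1L) stopf("internal: conv input shorter than kernel")
  Xm <- X; dim(Xm) <- c(n * L, Cin)
  Y <- matrix(b, n * Lout, Fo, byrow = TRUE)
  for (k in seq_len(K)) {
    rows <- ((k - 1L) * n + 1L):((k - 1L + Lout) * n)
    Y <- Y + Xm[rows, , drop = FALSE] %*% matrix(W[k, , ], Cin, Fo)
  }
  dim(Y) <- c(n, Lout, Fo)
  Y
}

conv1d_backward <- function(X, W, dY) {
  dms <- dim(X); n <- dms[1]; L <- dms[2]; Cin <- dms[3]
  K <- dim(W)[1]; Fo <- dim(W)[3]
  Lout <- L - K + 1L
  Xm <- X; dim(Xm) <- c(n * L, Cin)
  dYm <- dY; dim(dYm) <- c(n * Lout, Fo)
  dW <- array(0, dim(W)); db <- colSums(dYm)
  dXm <- matrix(0, n * L, Cin)
  for (k in seq_len(K)) {
    rows <- ((k - 1L) * n + 1L):((k - 1L + Lout) * n)
    dW[k, , ] <- crossprod(Xm[rows, , drop = FALSE], dYm)
    dXm[rows, ] <- dXm[rows, , drop = FALSE] +
      dYm %*% t(matrix(W[k, , ], Cin, Fo))
  }
  dim(dXm) <- c(n, L, Cin)
  list(dX = dXm, dW = dW, db = db)
}

maxpool_time <- function(A) {
  dms <- dim(A); n <- dms[1]; L <- dms[2]; Fo <- dms[3]
  Am <- A; dim(Am) <- c(n * L, Fo)
  M <- Am[seq_len(n), , drop = FALSE]
  idx <- matrix(1L, n, Fo)
  if (L > 1L) for (l in 2:L) {
    Al <- Am[((l - 1L) * n + 1L):(l * n), , drop = FALSE]
    better <- Al > M
    if (any(better)) {
      M[better] <- Al[better]
      idx[better] <- l
    }
  }
  list(M = M, idx = idx)
}

maxpool_backward <- function(dM, idx, L) {
  n <- nrow(dM); Fo <- ncol(dM)
  dA <- array(0, c(n, L, Fo))
  lin <- rep(seq_len(n), Fo) + (as.integer(idx) - 1L) * n +
    (rep(seq_len(Fo), each = n) - 1L) * (n * L)
  dA[lin] <- as.double(dM)
  dA
}

# ---- local head: embedding -> 3x(conv+ReLU) -> max-over-time ----

local_head_forward <- function(tokens, emb, convs) {
  kernels <- vapply(convs, function(l) dim(l$W)[1], integer(1))
  len <- rowSums(tokens != 0L)
  crop <- min(ncol(tokens), max(max(len), 1L) + sum(kernels - 1L) + 1L)
  crop <- max(crop, sum(kernels - 1L) + 1L)
  T <- tokens[, seq_len(crop), drop = FALSE]
  X0 <- embed_tokens(T, emb)
  Z1 <- conv1d_forward(X0, convs[[1]]$W, convs[[1]]$b); A1 <- relu(Z1)
  Z2 <- conv1d_forward(A1, convs[[2]]$W, convs[[2]]$b); A2 <- relu(Z2)
  Z3 <- conv1d_forward(A2, convs[[3]]$W, convs[[3]]$b); A3 <- relu(Z3)
  pool <- maxpool_time(A3)
  list(h = pool$M,
       cache = list(T = T, X0 = X0, A1 = A1, A2 = A2, A3 = A3,
                    Z1 = Z1, Z2 = Z2, Z3 = Z3, idx = pool$idx))
}

local_head_backward <- function(dh, cache, emb, convs) {
  dA3 <- maxpool_backward(dh, cache$idx, dim(cache$A3)[2])
  dZ3 <- dA3 * (cache$Z3 > 0)
  g3 <- conv1d_backward(cache$A2, convs[[3]]$W, dZ3)
  dZ2 <- g3$dX * (cache$Z2 > 0)
  g2 <- conv1d_backward(cache$A1, convs[[2]]$W, dZ2)
  dZ1 <- g2$dX * (cache$Z1 > 0)
  g1 <- conv1d_backward(cache$X0, convs[[1]]$W, dZ1)
  demb <- embed_backward(cache$T, g1$dX, nrow(emb))
  list(demb = demb,
       dconvs = list(list(dW = g1$dW, db = g1$db),
                     list(dW = g2$dW, db = g2$db),
                     list(dW = g3$dW, db = g3$db)))
}

# ---- full network ----

nn_forward <- function(params, batch, dropout = 0, train = FALSE,
                       keep_cache = FALSE) {
  lc <- local_head_forward(batch$comp_tokens, params$emb_c, params$conv_c)
  lp <- local_head_forward(batch$prot_tokens, params$emb_p, params$conv_p)
  Zgc <- batch$comp_global %*% params$dense_gc$W +
    matrix(params$dense_gc$b, nrow(batch$comp_global),
           length(params$dense_gc$b), byrow = TRUE)
  Agc <- relu(Zgc)
  Zgp <- batch$prot_global %*% params$dense_gp$W +
    matrix(params$dense_gp$b, nrow(batch$prot_global),
           length(params$dense_gp$b), byrow = TRUE)
  Agp <- relu(Zgp)
  Z <- cbind(lc$h, Agc, lp$h, Agp)

  n <- nrow(Z)
  masks <- list()
  H <- Z
  acts <- list()
  for (j in seq_along(params$fusion)) {
    lay <- params$fusion[[j]]
    Zi <- H %*% lay$W + matrix(lay$b, n, length(lay$b), byrow = TRUE)
    Ai <- relu(Zi)
    if (train && dropout > 0) {
      m <- matrix((stats::runif(length(Ai)) >= dropout) / (1 - dropout),
                  n, ncol(Ai))
      Ai <- Ai * m
      masks[[j]] <- m
    }
    acts[[j]] <- list(Z = Zi, A = Ai, input = H)
    H <- Ai
  }
  yhat <- drop(H %*% params$out$W) + params$out$b

  if (!keep_cache) return(list(yhat = yhat))
  list(yhat = yhat,
       cache = list(lc = lc, lp = lp, Zgc = Zgc, Agc = Agc, Zgp = Zgp,
                    Agp = Agp, Z = Z, acts = acts, masks = masks,
                    H_last = H))
}

nn_backward <- function(params, batch, cache, dyhat) {
  n <- length(dyhat)
  grads <- list()
  dy <- matrix(dyhat, n, 1)
  grads$out <- list(W = crossprod(cache$H_last, dy), db = sum(dy))
  dH <- dy %*% t(params$out$W)
  nf <- length(params$fusion)
  gf <- vector("list", nf)
  for (j in rev(seq_len(nf))) {
    a <- cache$acts[[j]]
    if (length(cache$masks) >= j && !is.null(cache$masks[[j]]))
      dH <- dH * cache$masks[[j]]
    dZ <- dH * (a$Z > 0)
    gf[[j]] <- list(dW = crossprod(a$input, dZ), db = colSums(dZ))
    dH <- dZ %*% t(params$fusion[[j]]$W)
  }
  grads$fusion <- gf
  # split concatenation gradient back into the four heads
  w_lc <- ncol(cache$lc$h); w_gc <- ncol(cache$Agc)
  w_lp <- ncol(cache$lp$h); w_gp <- ncol(cache$Agp)
  i1 <- seq_len(w_lc)
  i2 <- w_lc + seq_len(w_gc)
  i3 <- w_lc + w_gc + seq_len(w_lp)
  i4 <- w_lc + w_gc + w_lp + seq_len(w_gp)
  dZc <- dH[, i2, drop = FALSE] * (cache$Zgc > 0)
  grads$dense_gc <- list(dW = crossprod(batch$comp_global, dZc),
                         db = colSums(dZc))
  dZp <- dH[, i4, drop = FALSE] * (cache$Zgp > 0)
  grads$dense_gp <- list(dW = crossprod(batch$prot_global, dZp),
                         db = colSums(dZp))
  gl_c <- local_head_backward(dH[, i1, drop = FALSE], cache$lc$cache,
                              params$emb_c, params$conv_c)
  gl_p <- local_head_backward(dH[, i3, drop = FALSE], cache$lp$cache,
                              params$emb_p, params$conv_p)
  grads$emb_c <- gl_c$demb
  grads$emb_p <- gl_p$demb
  grads$conv_c <- gl_c$dconvs
  grads$conv_p <- gl_p$dconvs
  grads
}

# ---- parameter initialization ----

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)

init_conv <- function(K, Cin, Fo) {
  list(W = array(stats::rnorm(K * Cin * Fo, sd = sqrt(2 / (K * Cin))),
                 c(K, Cin, Fo)),
       b = numeric(Fo))
}

init_params <- function(config) {
  cf <- config
  E <- cf$embedding_dim
  filters <- cf$conv_filters
  params <- list()
  params$emb_c <- matrix(stats::runif(cf$compound_vocab_size * E, -0.05, 0.05),
                         cf$compound_vocab_size, E)
  params$emb_p <- matrix(stats::runif(cf$protein_vocab_size * E, -0.05, 0.05),
                         cf$protein_vocab_size, E)
  mk_convs <- function(kernels) {
    cins <- c(E, filters[1], filters[2])
    lapply(1:3, function(i) init_conv(kernels[i], cins[i], filters[i]))
  }
  params$conv_c <- mk_convs(cf$compound_kernels)
  params$conv_p <- mk_convs(cf$protein_kernels)
  params$dense_gc <- list(W = he_init(cf$compound_global_in,
                                      cf$compound_global_out,
                                      cf$compound_global_in),
                          b = numeric(cf$compound_global_out))
  params$dense_gp <- list(W = he_init(cf$protein_global_in,
                                      cf$protein_global_out,
                                      cf$protein_global_in),
                          b = numeric(cf$protein_global_out))
  widths <- c(concat_width(cf), cf$fusion_hidden)
  params$fusion <- lapply(seq_along(cf$fusion_hidden), function(j) {
    list(W = he_init(widths[j], widths[j + 1], widths[j]),
         b = numeric(widths[j + 1]))
  })
  last <- widths[length(widths)]
  params$out <- list(W = matrix(stats::rnorm(last, sd = sqrt(1 / last)),
                                last, 1),
                     b = 0)
  params
}

# ---- Adam on a nested parameter list ----

zeros_like <- function(x) {
  if (is.list(x)) return(lapply(x, zeros_like))
  y <- x; y[] <- 0; y
}

adam_init <- function(params) list(m = zeros_like(params),
                                   v = zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      # match by name where grad lists carry the parameter names; leaf
      # pairs named dW/db vs W/b (and unnamed layer lists) recurse
      # positionally in construction order
      by_name <- !is.null(names(p)) && !is.null(names(g)) &&
        all(names(p) %in% names(g))
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        gi <- if (by_name) g[[names(p)[i]]] else g[[i]]
        r <- upd(p[[i]], gi, m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
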