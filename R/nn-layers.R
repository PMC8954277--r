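# Neural-network primitives (forward + backward) on plain matrices.
#
# Convolutions act along the row (atom-order) axis of an N x C matrix via
# im2col, so every layer reduces to BLAS matrix products. All per-sample
# normalization uses per-channel statistics over the rows of the current
# sample (deterministic, batch-size independent); layers record what the
# backward pass needs in a small cache list.

# column-broadcast helpers (avoid sweep/aperm overhead in hot paths)
add_col <- function(X, v) X + rep(v, each = nrow(X))
mul_col <- function(X, v) X * rep(v, each = nrow(X))

he_weight <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
         nrow = fan_in, ncol = fan_out)
}

# -- 1D convolution (same padding, optional dilation) -------------------------

conv1d_fw <- function(X, W, b, k, dilation = 1) {
  n <- nrow(X); cin <- ncol(X)
  X0 <- rbind(X, 0)                      # row n+1 is the zero pad
  half <- (k + 1) / 2
  Xcol <- matrix(0, nrow = n, ncol = k * cin)
  src_list <- vector("list", k)
  for (t in seq_len(k)) {
    off <- (t - half) * dilation
    src <- seq_len(n) + off
    src[src < 1 | src > n] <- n + 1L
    src_list[[t]] <- src
    Xcol[, (t - 1) * cin + seq_len(cin)] <- X0[src, , drop = FALSE]
  }
  out <- add_col(Xcol %*% W, b)
  list(out = out, cache = list(Xcol = Xcol, src = src_list, k = k,
                               cin = cin, n = n))
}

conv1d_bw <- function(dout, W, cache) {
  dW <- crossprod(cache$Xcol, dout)
  db <- colSums(dout)
  dXcol <- dout %*% t(W)
  n <- cache$n; cin <- cache$cin
  dX <- matrix(0, nrow = n, ncol = cin)
  for (t in seq_len(cache$k)) {
    src <- cache$src[[t]]
    valid <- which(src <= n)
    if (length(valid)) {
      cols <- (t - 1) * cin + seq_len(cin)
      piece <- dXcol[valid, cols, drop = FALSE]
      tgt <- src[valid]
      dX[tgt, ] <- dX[tgt, , drop = FALSE] + piece
    }
  }
  list(dX = dX, dW = dW, db = db)
}

# -- per-channel normalization over rows --------------------------------------

chan_norm_fw <- function(X, gamma, beta, eps = 1e-5) {
  n <- nrow(X)
  mu <- colMeans(X)
  xc <- add_col(X, -mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  y <- mul_col(xc, inv)
  out <- add_col(mul_col(y, gamma), beta)
  list(out = out, cache = list(y = y, inv = inv, n = n, gamma = gamma))
}

chan_norm_bw <- function(dout, cache) {
  y <- cache$y; n <- cache$n
  dgamma <- colSums(dout * y)
  dbeta <- colSums(dout)
  dy <- mul_col(dout, cache$gamma)
  s1 <- colMeans(dy)
  s2 <- colMeans(dy * y)
  dX <- mul_col(add_col(dy, -s1) - mul_col(y, s2), cache$inv)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(X) {
  out <- pmax(X, 0)
  list(out = out, cache = X > 0)
}

relu_bw <- function(dout, mask) dout * mask

# -- inception block: parallel convs (kernels 1,3,5,7) + norm + ReLU ----------

init_inception <- function(cin, kernel_sizes, filters_per_branch) {
  convs <- lapply(kernel_sizes, function(k)
    list(W = he_weight(k * cin, filters_per_branch),
         b = numeric(filters_per_branch)))
  cout <- length(kernel_sizes) * filters_per_branch
  list(convs = convs, gamma = rep(1, cout), beta = numeric(cout))
}

inception_fw <- function(X, p, kernel_sizes, dilation = 1, normalize = TRUE) {
  branches <- vector("list", length(p$convs))
  outs <- vector("list", length(p$convs))
  for (i in seq_along(p$convs)) {
    cf <- conv1d_fw(X, p$convs[[i]]$W, p$convs[[i]]$b,
                    kernel_sizes[i], dilation)
    branches[[i]] <- cf$cache
    outs[[i]] <- cf$out
  }
  cat_out <- do.call(cbind, outs)
  if (normalize) {
    nf <- chan_norm_fw(cat_out, p$gamma, p$beta)
    act <- nf$out
    norm_cache <- nf$cache
  } else {
    act <- cat_out
    norm_cache <- NULL
  }
  rf <- relu_fw(act)
  list(out = rf$out,
       cache = list(branches = branches, norm = norm_cache, relu = rf$cache,
                    fpb = ncol(outs[[1]])))
}

inception_bw <- function(dout, p, cache) {
  d <- relu_bw(dout, cache$relu)
  if (!is.null(cache$norm)) {
    nb <- chan_norm_bw(d, cache$norm)
  } else {
    nb <- list(dX = d, dgamma = 0 * p$gamma, dbeta = 0 * p$beta)
  }
  fpb <- cache$fpb
  dX <- NULL
  gconvs <- vector("list", length(p$convs))
  for (i in seq_along(p$convs)) {
    cols <- (i - 1) * fpb + seq_len(fpb)
    cb <- conv1d_bw(nb$dX[, cols, drop = FALSE], p$convs[[i]]$W,
                    cache$branches[[i]])
    gconvs[[i]] <- list(W = cb$dW, b = cb$db)
    dX <- if (is.null(dX)) cb$dX else dX + cb$dX
  }
  list(dX = dX, grads = list(convs = gconvs, gamma = nb$dgamma,
                             beta = nb$dbeta))
}

# -- dense layer --------------------------------------------------------------

dense_fw <- function(X, W, b, activation = "relu") {
  z <- add_col(X %*% W, b)
  if (activation == "relu") {
    rf <- relu_fw(z)
    list(out = rf$out, cache = list(X = X, relu = rf$cache))
  } else {
    list(out = z, cache = list(X = X, relu = NULL))
  }
}

dense_bw <- function(dout, W, cache) {
  if (!is.null(cache$relu)) dout <- relu_bw(dout, cache$relu)
  list(dX = dout %*% t(W), dW = crossprod(cache$X, dout), db = colSums(dout))
}

# -- max pooling by 2 along rows ----------------------------------------------

maxpool2_fw <- function(X) {
  n <- nrow(X)
  stopifnot(n %% 2 == 0)
  a <- X[seq(1, n, by = 2), , drop = FALSE]
  b <- X[seq(2, n, by = 2), , drop = FALSE]
  take_a <- a >= b
  list(out = ifelse(take_a, a, b), cache = list(take_a = take_a, n = n))
}

maxpool2_bw <- function(dout, cache) {
  n <- cache$n
  dX <- matrix(0, nrow = n, ncol = ncol(dout))
  dX[seq(1, n, by = 2), ] <- dout * cache$take_a
  dX[seq(2, n, by = 2), ] <- dout * !cache$take_a
  dX
}

# -- region max pool over contiguous K-row blocks -----------------------------
# Z is (S*K) x F with region-major rows; returns S x F plus argmax rows.

region_maxpool_fw <- function(Z, S, K) {
  f <- ncol(Z)
  base <- (seq_len(S) - 1L) * K
  out <- Z[base + 1L, , drop = FALSE]
  arg <- matrix(base + 1L, nrow = S, ncol = f)
  for (k in seq_len(K)[-1]) {
    M <- Z[base + k, , drop = FALSE]
    upd <- M > out                              # strict: first max wins ties
    if (any(upd)) {
      out[upd] <- M[upd]
      arg[upd] <- matrix(base + k, nrow = S, ncol = f)[upd]
    }
  }
  list(out = out, cache = list(arg = arg, nrow = S * K))
}

region_maxpool_bw <- function(dout, cache) {
  f <- ncol(dout); S <- nrow(dout)
  dZ <- matrix(0, nrow = cache$nrow, ncol = f)
  dZ[cbind(as.vector(cache$arg), rep(seq_len(f), each = S))] <- as.vector(dout)
  dZ
}

# -- softmax + categorical cross-entropy --------------------------------------

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# logits: 1 x C matrix or length-C vector; label: 1-based class index.
ce_loss <- function(logits, label) {
  p <- softmax_vec(as.numeric(logits))
  loss <- -log(max(p[label], 1e-12))
  dlogits <- p
  dlogits[label] <- dlogits[label] - 1
  list(loss = loss, dlogits = matrix(dlogits, nrow = 1), p = p)
}
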