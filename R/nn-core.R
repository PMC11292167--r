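# Minimal dense neural-network primitives with explicit forward caches and
# analytic backward passes, written against base-R matrix ops (BLAS does the
# heavy lifting). Conventions:
#   * time-expanded matrices are (B*T) x F with row index r = b + (t-1)*B
#     ("bt layout": batch fastest), which matches R's column-major reshapes;
#   * every nn_*_forward returns list(out, cache); nn_*_backward takes the
#     upstream gradient plus the cache and returns list(dx, grads), grads
#     being a named list aligned with the parameter names.
# Gradient correctness is finite-difference tested in the unit suite.

# broadcast a length-F vector across the rows of an n x F matrix
.addrow <- function(M, v) M + rep(v, each = nrow(M))
.mulrow <- function(M, v) M * rep(v, each = nrow(M))

nn_linear_forward <- function(X, W, b) {
  list(out = .addrow(X %*% W, b), cache = X)
}

nn_linear_backward <- function(dY, cache, W) {
  list(dx = dY %*% t(W),
       dW = crossprod(cache, dY),
       db = colSums(dY))
}

# exact GELU: x * pnorm(x) (C++ kernel)
nn_gelu_forward <- function(X) list(out = .cpp_gelu_forward(X), cache = X)

nn_gelu_backward <- function(dY, cache) .cpp_gelu_backward(dY, cache)

# batch normalization over columns (per feature, across batch*time rows)
nn_bn_forward <- function(X, gamma, beta, run, training, momentum = 0.1,
                          eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- .addrow(X, -mu)
    va <- colMeans(xc^2)
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * va
  } else {
    mu <- run$mean; va <- run$var
    xc <- .addrow(X, -mu)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- .mulrow(xc, inv)
  out <- .addrow(.mulrow(xhat, gamma), beta)
  list(out = out, run = run,
       cache = list(xhat = xhat, inv = inv, xc = xc, training = training))
}

nn_bn_backward <- function(dY, cache, gamma) {
  xhat <- cache$xhat; inv <- cache$inv
  n <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- .mulrow(dY, gamma)
  if (cache$training) {
    # dx = inv/n * (n*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
    t2 <- rep(colSums(dxhat), each = n)
    t3 <- xhat * rep(colSums(dxhat * xhat), each = n)
    dx <- .mulrow(n * dxhat - t2 - t3, inv / n)
  } else {
    dx <- .mulrow(dxhat, inv)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# layer normalization per row
nn_ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  out <- .addrow(.mulrow(xhat, g), b)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

nn_ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  d <- ncol(dY)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- .mulrow(dY, g)
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

# 1D convolution, same padding, single input channel -> F filters
# (C++ kernels; layout (B*L) x F, bt order). x: B x L; W: k x F.
nn_conv1d_forward <- function(x, W, b) {
  list(out = .cpp_conv1d_forward(x, W, b), cache = list(x = x))
}

nn_conv1d_backward <- function(dY, cache, W) {
  .cpp_conv1d_backward(cache$x, dY, W)
}

# max pooling kernel = stride = k over time: (B*L) x F -> (B*N) x F, N = L/k
nn_maxpool_forward <- function(X, B, k) {
  r <- .cpp_maxpool_forward(X, B, k)
  list(out = r$out, cache = list(amax = r$amax, B = B, k = k))
}

nn_maxpool_backward <- function(dY, cache) {
  .cpp_maxpool_backward(dY, cache$amax, cache$B, cache$k)
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# multi-head self-attention over tokens in bt layout
nn_mhsa_forward <- function(X, p, pre, B, N, h) {
  d <- ncol(X); dh <- d %/% h; s <- sqrt(dh)
  Q <- .addrow(X %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
  K <- .addrow(X %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
  V <- .addrow(X %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
  O <- matrix(0, B * N, d)
  A <- vector("list", B * h)
  for (b in seq_len(B)) {
    rows <- b + (0:(N - 1L)) * B
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dh + 1L):(i * dh)
      Si <- (Q[rows, cols, drop = FALSE] %*%
               t(K[rows, cols, drop = FALSE])) / s
      Ai <- .softmax_rows(Si)
      A[[(b - 1L) * h + i]] <- Ai
      O[rows, cols] <- Ai %*% V[rows, cols, drop = FALSE]
    }
  }
  out <- .addrow(O %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, O = O, A = A,
                               B = B, N = N, h = h, dh = dh, s = s))
}

nn_mhsa_backward <- function(dY, cache, p, pre) {
  X <- cache$X; Q <- cache$Q; K <- cache$K; V <- cache$V; O <- cache$O
  B <- cache$B; N <- cache$N; h <- cache$h; dh <- cache$dh; s <- cache$s
  d <- ncol(X)
  dWo <- crossprod(O, dY); dbo <- colSums(dY)
  dO <- dY %*% t(p[[paste0(pre, "Wo")]])
  dQ <- matrix(0, B * N, d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- b + (0:(N - 1L)) * B
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dh + 1L):(i * dh)
      Ai <- cache$A[[(b - 1L) * h + i]]
      dOi <- dO[rows, cols, drop = FALSE]
      Vi <- V[rows, cols, drop = FALSE]
      dAi <- dOi %*% t(Vi)
      dV[rows, cols] <- crossprod(Ai, dOi)
      dSi <- Ai * (dAi - rowSums(dAi * Ai))
      dQ[rows, cols] <- (dSi %*% K[rows, cols, drop = FALSE]) / s
      dK[rows, cols] <- (crossprod(dSi, Q[rows, cols, drop = FALSE])) / s
    }
  }
  dX <- dQ %*% t(p[[paste0(pre, "Wq")]]) +
    dK %*% t(p[[paste0(pre, "Wk")]]) +
    dV %*% t(p[[paste0(pre, "Wv")]])
  grads <- list(crossprod(X, dQ), colSums(dQ),
                crossprod(X, dK), colSums(dK),
                crossprod(X, dV), colSums(dV), dWo, dbo)
  names(grads) <- paste0(pre, c("Wq", "bq", "Wk", "bk", "Wv", "bv",
                                "Wo", "bo"))
  list(dx = dX, grads = grads)
}

nn_dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  keep <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X))
  list(out = X * keep / (1 - p), cache = list(keep = keep, p = p))
}

nn_dropout_backward <- function(dY, cache) {
  if (is.null(cache)) return(dY)
  dY * cache$keep / (1 - cache$p)
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' AdamW optimizer state
#'
#' Decoupled weight decay Adam. `adamwStep()` updates parameters in place
#' (returns the new parameter list and mutated state).
#'
#' @param params named list of numeric arrays.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment coefficients.
#' @param weight_decay decoupled weight decay (applied to matrices, not
#'   biases/norm parameters).
#' @return An optimizer state list.
#' @export
adamwInit <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0.01) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

#' @rdname adamwInit
#' @param opt optimizer state from [adamwInit()].
#' @param grads named list of gradients (subset of parameter names).
#' @param trainable names of parameters allowed to move (default: all with
#'   gradients).
#' @export
adamwStep <- function(params, grads, opt, trainable = names(grads)) {
  opt$t <- opt$t + 1L
  b1t <- 1 - opt$beta1^opt$t
  b2t <- 1 - opt$beta2^opt$t
  for (nm in intersect(trainable, names(grads))) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    step <- (opt$m[[nm]] / b1t) / (sqrt(opt$v[[nm]] / b2t) + opt$eps)
    wd <- if (is.matrix(params[[nm]])) opt$weight_decay else 0
    params[[nm]] <- params[[nm]] - opt$lr * (step + wd * params[[nm]])
  }
  list(params = params, opt = opt)
}
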