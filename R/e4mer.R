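#' @include nn-core.R synth.R
NULL

#' Configuration of the multirate channel-embedding transformer
#'
#' Per channel, a 1D convolution with kernel size equal to the channel
#' sampling rate, GELU, 1D batch normalization and max pooling (kernel =
#' stride = sampling rate) reduces every channel to exactly one token per
#' second (`N = omega` tokens) with `n_filters` features; the six channel
#' embeddings are concatenated, linearly projected to `d_model`, given learned
#' positional embeddings, and fed to a post-norm transformer encoder.
#' Interchangeable heads map the representations to class probabilities,
#' per-channel reconstructions, or per-channel transformation logits.
#'
#' The default is a deliberately small, CPU-trainable configuration; a
#' larger-scale configuration is a matter of raising `n_filters`, `d_model`,
#' `n_layers` and `mlp_hidden`.
#'
#' @param fs named per-channel sampling rates (Hz); kernel and pool sizes.
#' @param omega segment length in seconds (= token count).
#' @param n_filters convolution filters per channel embedding.
#' @param d_model transformer width; must be divisible by `n_heads`.
#' @param n_heads attention heads.
#' @param n_layers encoder layers.
#' @param mlp_hidden hidden width of the MLP heads and feed-forward blocks.
#' @param dropout dropout probability during training.
#' @param seed initialization seed.
#' @return A list of class `e4mer_config`.
#' @export
e4merConfig <- function(fs, omega, n_filters = 8, d_model = 64, n_heads = 4,
                        n_layers = 2, mlp_hidden = 64, dropout = 0,
                        seed = 1) {
  stopifnot(d_model %% n_heads == 0, omega >= 1, all(fs > 0))
  structure(list(fs = fs, omega = as.integer(omega), n_filters = n_filters,
                 d_model = d_model, n_heads = n_heads, n_layers = n_layers,
                 mlp_hidden = mlp_hidden, dropout = dropout, seed = seed),
            class = "e4mer_config")
}

.enc_param_names <- function(params) grep("^enc\\.", names(params), value = TRUE)

#' Initialize an E4mer model
#'
#' Glorot-uniform initialization of the encoder plus the requested head
#' (`classify`, `reconstruct` for masked prediction, or `transform_predict`).
#'
#' @param cfg an [e4merConfig()].
#' @param head head kind.
#' @return A model list: `cfg`, `params` (flat named list), `bn` (per-channel
#'   running statistics), `head`, `trainable` (parameter names updated during
#'   training), `freeze_bn`.
#' @export
e4merInit <- function(cfg, head = c("classify", "reconstruct",
                                    "transform_predict")) {
  head <- match.arg(head)
  stopifnot(inherits(cfg, "e4mer_config"))
  .with_seed(cfg$seed, {
    p <- list()
    Fn <- cfg$n_filters; d <- cfg$d_model; hdim <- cfg$mlp_hidden
    chs <- names(cfg$fs)
    for (ch in chs) {
      k <- as.integer(round(cfg$fs[[ch]]))
      p[[paste0("enc.ce_", ch, ".W")]] <- .glorot(k, Fn)
      p[[paste0("enc.ce_", ch, ".b")]] <- numeric(Fn)
      p[[paste0("enc.ce_", ch, ".gamma")]] <- rep(1, Fn)
      p[[paste0("enc.ce_", ch, ".beta")]] <- numeric(Fn)
    }
    p[["enc.proj.W"]] <- .glorot(length(chs) * Fn, d)
    p[["enc.proj.b"]] <- numeric(d)
    p[["enc.pos"]] <- matrix(stats::rnorm(cfg$omega * d, 0, 0.02),
                             cfg$omega, d)
    for (l in seq_len(cfg$n_layers)) {
      pre <- sprintf("enc.l%d.", l)
      for (w in c("Wq", "Wk", "Wv", "Wo"))
        p[[paste0(pre, "attn.", w)]] <- .glorot(d, d)
      for (b in c("bq", "bk", "bv", "bo"))
        p[[paste0(pre, "attn.", b)]] <- numeric(d)
      p[[paste0(pre, "ln1.g")]] <- rep(1, d)
      p[[paste0(pre, "ln1.b")]] <- numeric(d)
      p[[paste0(pre, "ffn.W1")]] <- .glorot(d, hdim)
      p[[paste0(pre, "ffn.b1")]] <- numeric(hdim)
      p[[paste0(pre, "ffn.W2")]] <- .glorot(hdim, d)
      p[[paste0(pre, "ffn.b2")]] <- numeric(d)
      p[[paste0(pre, "ln2.g")]] <- rep(1, d)
      p[[paste0(pre, "ln2.b")]] <- numeric(d)
    }
    p <- c(p, .head_params(cfg, head))
    bn <- lapply(stats::setNames(chs, chs), function(ch)
      list(mean = numeric(Fn), var = rep(1, Fn)))
    list(cfg = cfg, params = p, bn = bn, head = head,
         trainable = names(p), freeze_bn = FALSE)
  })
}

.head_params <- function(cfg, head) {
  d <- cfg$d_model; hdim <- cfg$mlp_hidden
  p <- list()
  if (head == "classify") {
    p[["head_cls.W1"]] <- .glorot(d, hdim)
    p[["head_cls.b1"]] <- numeric(hdim)
    p[["head_cls.W2"]] <- .glorot(hdim, 2L)
    p[["head_cls.b2"]] <- numeric(2L)
  } else if (head == "reconstruct") {
    for (ch in names(cfg$fs)) {
      k <- as.integer(round(cfg$fs[[ch]]))
      p[[paste0("head_mp.", ch, ".W")]] <- .glorot(d, k)
      p[[paste0("head_mp.", ch, ".b")]] <- numeric(k)
    }
  } else {
    p[["head_tp.W1"]] <- .glorot(d, hdim)
    p[["head_tp.b1"]] <- numeric(hdim)
    p[["head_tp.W2"]] <- .glorot(hdim, 6L * length(cfg$fs))
    p[["head_tp.b2"]] <- numeric(6L * length(cfg$fs))
  }
  p
}

#' Assemble a batch of segments into channel matrices
#'
#' @param segments a standardized [SegmentSet-class].
#' @param idx segment indices.
#' @return List with `x` (named list of B x L channel matrices), `label`
#'   (0/1, 1 = acute) and `subject_id`.
#' @export
segmentBatch <- function(segments, idx = seq_len(nSegments(segments))) {
  chs <- names(segments@fs)
  x <- lapply(stats::setNames(chs, chs), function(ch)
    do.call(rbind, lapply(segments@data[idx], `[[`, ch)))
  info <- segmentInfo(segments)[idx, , drop = FALSE]
  list(x = x, label = as.integer(info$label == "acute"),
       subject_id = info$subject_id)
}

## ---- encoder ---------------------------------------------------------------

.encoder_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg; p <- model$params
  B <- nrow(x[[1L]]); N <- cfg$omega
  bn_training <- training && !isTRUE(model$freeze_bn)
  caches <- list(B = B)
  toks <- list()
  for (ch in names(cfg$fs)) {
    k <- as.integer(round(cfg$fs[[ch]]))
    cv <- nn_conv1d_forward(x[[ch]], p[[paste0("enc.ce_", ch, ".W")]],
                            p[[paste0("enc.ce_", ch, ".b")]])
    ge <- nn_gelu_forward(cv$out)
    bn <- nn_bn_forward(ge$out, p[[paste0("enc.ce_", ch, ".gamma")]],
                        p[[paste0("enc.ce_", ch, ".beta")]],
                        model$bn[[ch]], bn_training)
    model$bn[[ch]] <- bn$run
    mp <- nn_maxpool_forward(bn$out, B, k)
    stopifnot(nrow(mp$out) == B * N)
    toks[[ch]] <- mp$out
    caches[[ch]] <- list(cv = cv$cache, ge = ge$cache, bn = bn$cache,
                         mp = mp$cache)
  }
  Tcat <- do.call(cbind, toks)
  pr <- nn_linear_forward(Tcat, p[["enc.proj.W"]], p[["enc.proj.b"]])
  X <- pr$out + p[["enc.pos"]][rep(seq_len(N), each = B), , drop = FALSE]
  dr0 <- nn_dropout_forward(X, cfg$dropout, training)
  X <- dr0$out
  lcache <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("enc.l%d.", l)
    at <- nn_mhsa_forward(X, p, paste0(pre, "attn."), B, N, cfg$n_heads)
    dr1 <- nn_dropout_forward(at$out, cfg$dropout, training)
    r1 <- X + dr1$out
    ln1 <- nn_ln_forward(r1, p[[paste0(pre, "ln1.g")]],
                         p[[paste0(pre, "ln1.b")]])
    f1 <- nn_linear_forward(ln1$out, p[[paste0(pre, "ffn.W1")]],
                            p[[paste0(pre, "ffn.b1")]])
    g1 <- nn_gelu_forward(f1$out)
    f2 <- nn_linear_forward(g1$out, p[[paste0(pre, "ffn.W2")]],
                            p[[paste0(pre, "ffn.b2")]])
    dr2 <- nn_dropout_forward(f2$out, cfg$dropout, training)
    r2 <- ln1$out + dr2$out
    ln2 <- nn_ln_forward(r2, p[[paste0(pre, "ln2.g")]],
                         p[[paste0(pre, "ln2.b")]])
    lcache[[l]] <- list(at = at$cache, dr1 = dr1$cache, ln1 = ln1$cache,
                        f1 = f1$cache, g1 = g1$cache, f2 = f2$cache,
                        dr2 = dr2$cache, ln2 = ln2$cache)
    X <- ln2$out
  }
  caches$proj <- pr$cache
  caches$dr0 <- dr0$cache
  caches$layers <- lcache
  list(out = X, cache = caches, model = model)
}

.encoder_backward <- function(dX, cache, model) {
  cfg <- model$cfg; p <- model$params
  B <- cache$B; N <- cfg$omega
  g <- list()
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("enc.l%d.", l)
    lc <- cache$layers[[l]]
    bl2 <- nn_ln_backward(dX, lc$ln2, p[[paste0(pre, "ln2.g")]])
    g[[paste0(pre, "ln2.g")]] <- bl2$dg
    g[[paste0(pre, "ln2.b")]] <- bl2$db
    dr2 <- bl2$dx
    df2 <- nn_dropout_backward(dr2, lc$dr2)
    b2 <- nn_linear_backward(df2, lc$f2, p[[paste0(pre, "ffn.W2")]])
    g[[paste0(pre, "ffn.W2")]] <- b2$dW
    g[[paste0(pre, "ffn.b2")]] <- b2$db
    dg1 <- nn_gelu_backward(b2$dx, lc$g1)
    b1 <- nn_linear_backward(dg1, lc$f1, p[[paste0(pre, "ffn.W1")]])
    g[[paste0(pre, "ffn.W1")]] <- b1$dW
    g[[paste0(pre, "ffn.b1")]] <- b1$db
    dln1_out <- b1$dx + dr2                    # residual around the FFN
    bl1 <- nn_ln_backward(dln1_out, lc$ln1, p[[paste0(pre, "ln1.g")]])
    g[[paste0(pre, "ln1.g")]] <- bl1$dg
    g[[paste0(pre, "ln1.b")]] <- bl1$db
    dr1 <- bl1$dx
    dat <- nn_dropout_backward(dr1, lc$dr1)
    ba <- nn_mhsa_backward(dat, lc$at, p, paste0(pre, "attn."))
    g <- c(g, ba$grads)
    dX <- ba$dx + dr1                          # residual around attention
  }
  dX <- nn_dropout_backward(dX, cache$dr0)
  # positional embeddings: sum gradient over the batch at each token
  idxn <- rep(seq_len(N), each = B)
  g[["enc.pos"]] <- rowsum(dX, idxn)
  bp <- nn_linear_backward(dX, cache$proj, p[["enc.proj.W"]])
  g[["enc.proj.W"]] <- bp$dW
  g[["enc.proj.b"]] <- bp$db
  Fn <- cfg$n_filters
  dxs <- list()
  for (ci in seq_along(cfg$fs)) {
    ch <- names(cfg$fs)[ci]
    cols <- ((ci - 1L) * Fn + 1L):(ci * Fn)
    dtok <- bp$dx[, cols, drop = FALSE]
    cc <- cache[[ch]]
    dbn_out <- nn_maxpool_backward(dtok, cc$mp)
    bb <- nn_bn_backward(dbn_out, cc$bn, p[[paste0("enc.ce_", ch, ".gamma")]])
    g[[paste0("enc.ce_", ch, ".gamma")]] <- bb$dgamma
    g[[paste0("enc.ce_", ch, ".beta")]] <- bb$dbeta
    dge <- nn_gelu_backward(bb$dx, cc$ge)
    bc <- nn_conv1d_backward(dge, cc$cv, p[[paste0("enc.ce_", ch, ".W")]])
    g[[paste0("enc.ce_", ch, ".W")]] <- bc$dW
    g[[paste0("enc.ce_", ch, ".b")]] <- bc$db
    dxs[[ch]] <- bc$dx
  }
  list(grads = g, dx = dxs)
}

.mean_pool <- function(X, B, N) {
  pooled <- matrix(0, B, ncol(X))
  for (n in seq_len(N)) pooled <- pooled + X[(n - 1L) * B + seq_len(B), ,
                                             drop = FALSE]
  pooled / N
}

.mean_pool_backward <- function(dpooled, B, N) {
  dX <- matrix(0, B * N, ncol(dpooled))
  for (n in seq_len(N)) dX[(n - 1L) * B + seq_len(B), ] <- dpooled / N
  dX
}

## ---- public forward operations ---------------------------------------------

#' Channel embeddings of a batch
#'
#' Runs only the per-channel embedding stack (conv, GELU, batch norm, max
#' pool) and concatenates the channel tokens.
#'
#' @param model an E4mer model.
#' @param x named list of B x L channel matrices (see [segmentBatch()]).
#' @return Token matrix `(B*N) x (channels * n_filters)` in bt layout with
#'   attribute `B`.
#' @export
channelEmbed <- function(model, x) {
  cfg <- model$cfg; p <- model$params
  B <- nrow(x[[1L]])
  toks <- list()
  for (ch in names(cfg$fs)) {
    k <- as.integer(round(cfg$fs[[ch]]))
    L <- ncol(x[[ch]])
    if (L != round(cfg$omega * cfg$fs[[ch]]))
      stop(sprintf("channel %s length %d incompatible with omega=%d at %g Hz",
                   ch, L, cfg$omega, cfg$fs[[ch]]))
    cv <- nn_conv1d_forward(x[[ch]], p[[paste0("enc.ce_", ch, ".W")]],
                            p[[paste0("enc.ce_", ch, ".b")]])
    ge <- nn_gelu_forward(cv$out)
    bn <- nn_bn_forward(ge$out, p[[paste0("enc.ce_", ch, ".gamma")]],
                        p[[paste0("enc.ce_", ch, ".beta")]],
                        model$bn[[ch]], training = FALSE)
    toks[[ch]] <- nn_maxpool_forward(bn$out, B, k)$out
  }
  out <- do.call(cbind, toks)
  attr(out, "B") <- B
  out
}

#' Encode a batch into contextual token representations
#'
#' @param model an E4mer model.
#' @param x named list of B x L channel matrices.
#' @param training training mode (enables dropout/batch statistics).
#' @return `(B*N) x d_model` matrix in bt layout with attribute `B`.
#' @export
encodeSegments <- function(model, x, training = FALSE) {
  fw <- .encoder_forward(model, x, training = training)
  out <- fw$out
  attr(out, "B") <- fw$cache$B
  out
}

#' Classify a batch of segments
#'
#' Mean-pools tokens, applies the MLP classification head and a softmax.
#'
#' @inheritParams encodeSegments
#' @return B x 2 matrix of class probabilities, columns `acute`, `euthymia`;
#'   rows sum to 1.
#' @export
classifySegments <- function(model, x) {
  stopifnot(model$head == "classify")
  fw <- .encoder_forward(model, x, training = FALSE)
  B <- fw$cache$B
  pooled <- .mean_pool(fw$out, B, model$cfg$omega)
  h1 <- nn_linear_forward(pooled, model$params[["head_cls.W1"]],
                          model$params[["head_cls.b1"]])
  a1 <- nn_gelu_forward(h1$out)
  lg <- nn_linear_forward(a1$out, model$params[["head_cls.W2"]],
                          model$params[["head_cls.b2"]])
  pr <- .softmax_rows(lg$out)
  colnames(pr) <- c("acute", "euthymia")
  pr
}

#' Reconstruct channel signals from representations
#'
#' Token-wise linear projection back to `fs[channel]` samples per second per
#' channel, giving native-length outputs.
#'
#' @inheritParams encodeSegments
#' @return Named list of B x (omega*fs) matrices.
#' @export
reconstructSegments <- function(model, x) {
  stopifnot(model$head == "reconstruct")
  fw <- .encoder_forward(model, x, training = FALSE)
  B <- fw$cache$B; N <- model$cfg$omega
  out <- list()
  for (ch in names(model$cfg$fs)) {
    k <- as.integer(round(model$cfg$fs[[ch]]))
    o <- nn_linear_forward(fw$out, model$params[[paste0("head_mp.", ch, ".W")]],
                           model$params[[paste0("head_mp.", ch, ".b")]])$out
    arr <- array(o, c(B, N, k))
    out[[ch]] <- matrix(aperm(arr, c(1L, 3L, 2L)), B, N * k)
  }
  out
}

#' Per-channel transformation logits
#'
#' @inheritParams encodeSegments
#' @return Array B x channels x 6 of logits.
#' @export
predictTransforms <- function(model, x) {
  stopifnot(model$head == "transform_predict")
  fw <- .encoder_forward(model, x, training = FALSE)
  B <- fw$cache$B
  pooled <- .mean_pool(fw$out, B, model$cfg$omega)
  h1 <- nn_linear_forward(pooled, model$params[["head_tp.W1"]],
                          model$params[["head_tp.b1"]])
  a1 <- nn_gelu_forward(h1$out)
  lg <- nn_linear_forward(a1$out, model$params[["head_tp.W2"]],
                          model$params[["head_tp.b2"]])$out
  C <- length(model$cfg$fs)
  arr <- array(0, c(B, C, 6L))
  for (ci in seq_len(C)) arr[, ci, ] <- lg[, ((ci - 1L) * 6L + 1L):(ci * 6L)]
  dimnames(arr) <- list(NULL, names(model$cfg$fs), transformKinds())
  arr
}

#' Transfer a pretrained encoder to the classification task
#'
#' Discards the pretext head, attaches a freshly initialized classification
#' head, and sets the training regime: linear readout (`"lr"`) freezes every
#' encoder parameter and the batch-norm statistics, so encoder outputs are
#' bit-identical before and after target training; fine-tuning (`"ft"`) leaves
#' all parameters trainable, initialized from pretraining.
#'
#' @param model a pretrained E4mer model (any head).
#' @param mode `"lr"` or `"ft"`.
#' @param head_seed seed for the fresh head initialization.
#' @return A model with `head = "classify"`.
#' @export
transferModel <- function(model, mode = c("lr", "ft"), head_seed = 1) {
  mode <- match.arg(mode)
  model$params <- model$params[.enc_param_names(model$params)]
  new_head <- .with_seed(head_seed, .head_params(model$cfg, "classify"))
  model$params <- c(model$params, new_head)
  model$head <- "classify"
  if (mode == "lr") {
    model$trainable <- names(new_head)
    model$freeze_bn <- TRUE
  } else {
    model$trainable <- names(model$params)
    model$freeze_bn <- FALSE
  }
  model
}

## ---- loss + gradients for the three tasks ----------------------------------

# returns list(loss, grads, aux); labels: 0/1 (1 = acute) for classify;
# masks/original for mp; assignment matrix (B x C) for tp
.e4mer_loss_grads <- function(model, x, target, training = TRUE) {
  cfg <- model$cfg
  fw <- .encoder_forward(model, x, training = training)
  model <- fw$model                    # batch-norm running stats updated
  B <- fw$cache$B; N <- cfg$omega
  p <- model$params

  if (model$head == "classify") {
    y <- target$label
    pooled <- .mean_pool(fw$out, B, N)
    h1 <- nn_linear_forward(pooled, p[["head_cls.W1"]], p[["head_cls.b1"]])
    a1 <- nn_gelu_forward(h1$out)
    lg <- nn_linear_forward(a1$out, p[["head_cls.W2"]], p[["head_cls.b2"]])
    pr <- .softmax_rows(lg$out)
    eps <- 1e-12
    loss <- -mean(y * log(pr[, 1] + eps) + (1 - y) * log(pr[, 2] + eps))
    onehot <- cbind(y, 1 - y)
    dlg <- (pr - onehot) / B
    g <- list()
    b2 <- nn_linear_backward(dlg, lg$cache, p[["head_cls.W2"]])
    g[["head_cls.W2"]] <- b2$dW; g[["head_cls.b2"]] <- b2$db
    da1 <- nn_gelu_backward(b2$dx, a1$cache)
    b1 <- nn_linear_backward(da1, h1$cache, p[["head_cls.W1"]])
    g[["head_cls.W1"]] <- b1$dW; g[["head_cls.b1"]] <- b1$db
    dX <- .mean_pool_backward(b1$dx, B, N)
    eb <- .encoder_backward(dX, fw$cache, model)
    list(loss = loss, grads = c(g, eb$grads), model = model,
         probs = pr[, 1])
  } else if (model$head == "reconstruct") {
    masks <- target$masks; orig <- target$original
    g <- list(); sq <- 0; m <- 0
    head_caches <- list(); douts <- list()
    for (ch in names(cfg$fs)) {
      k <- as.integer(round(cfg$fs[[ch]]))
      hf <- nn_linear_forward(fw$out, p[[paste0("head_mp.", ch, ".W")]],
                              p[[paste0("head_mp.", ch, ".b")]])
      arr <- array(hf$out, c(B, N, k))
      xhat <- matrix(aperm(arr, c(1L, 3L, 2L)), B, N * k)
      head_caches[[ch]] <- hf$cache
      diff <- (xhat - orig[[ch]]) * masks[[ch]]
      sq <- sq + sum(diff^2); m <- m + sum(masks[[ch]])
      douts[[ch]] <- diff
    }
    if (m == 0) stop("masked RMSE undefined: empty mask in batch")
    loss <- sqrt(sq / m)
    dX <- matrix(0, B * N, cfg$d_model)
    for (ch in names(cfg$fs)) {
      k <- as.integer(round(cfg$fs[[ch]]))
      dxhat <- douts[[ch]] / (m * loss)
      darr <- aperm(array(dxhat, c(B, k, N)), c(1L, 3L, 2L))
      dHo <- matrix(darr, B * N, k)
      bh <- nn_linear_backward(dHo, head_caches[[ch]],
                               p[[paste0("head_mp.", ch, ".W")]])
      g[[paste0("head_mp.", ch, ".W")]] <- bh$dW
      g[[paste0("head_mp.", ch, ".b")]] <- bh$db
      dX <- dX + bh$dx
    }
    eb <- .encoder_backward(dX, fw$cache, model)
    list(loss = loss, grads = c(g, eb$grads), model = model)
  } else {
    assign_mat <- target$assignment       # B x C kinds
    C <- length(cfg$fs)
    pooled <- .mean_pool(fw$out, B, N)
    h1 <- nn_linear_forward(pooled, p[["head_tp.W1"]], p[["head_tp.b1"]])
    a1 <- nn_gelu_forward(h1$out)
    lgf <- nn_linear_forward(a1$out, p[["head_tp.W2"]], p[["head_tp.b2"]])
    lg <- lgf$out
    loss <- 0
    dlg <- matrix(0, B, 6L * C)
    for (ci in seq_len(C)) {
      cols <- ((ci - 1L) * 6L + 1L):(ci * 6L)
      pr <- .softmax_rows(lg[, cols, drop = FALSE])
      yy <- assign_mat[, ci]
      loss <- loss - sum(log(pr[cbind(seq_len(B), yy)] + 1e-12))
      oh <- matrix(0, B, 6L); oh[cbind(seq_len(B), yy)] <- 1
      dlg[, cols] <- (pr - oh) / (B * C)
    }
    loss <- loss / (B * C)
    g <- list()
    b2 <- nn_linear_backward(dlg, lgf$cache, p[["head_tp.W2"]])
    g[["head_tp.W2"]] <- b2$dW; g[["head_tp.b2"]] <- b2$db
    da1 <- nn_gelu_backward(b2$dx, a1$cache)
    b1 <- nn_linear_backward(da1, h1$cache, p[["head_tp.W1"]])
    g[["head_tp.W1"]] <- b1$dW; g[["head_tp.b1"]] <- b1$db
    dX <- .mean_pool_backward(b1$dx, B, N)
    eb <- .encoder_backward(dX, fw$cache, model)
    list(loss = loss, grads = c(g, eb$grads), model = model)
  }
}
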