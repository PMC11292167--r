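tiny_fs <- c(acc_x = 4, acc_y = 4, acc_z = 4, bvp = 8, eda = 2, temp = 1)

tiny_cfg <- function(...) e4merConfig(tiny_fs, omega = 6, n_filters = 3,
                                      d_model = 8, n_heads = 2, n_layers = 2,
                                      mlp_hidden = 5, seed = 7, ...)

rand_x <- function(B, fs = tiny_fs, omega = 6, seed = 42) {
  set.seed(seed)
  lapply(fs, function(f) matrix(rnorm(B * omega * f), B))
}

test_that("every channel embedding emits exactly omega tokens", {
  # token-count invariant across the native rates 1/4/32/64
  fs <- c(acc_x = 32, acc_y = 32, acc_z = 32, bvp = 64, eda = 4, temp = 1)
  cfg <- e4merConfig(fs, omega = 8, n_filters = 2, d_model = 8, n_heads = 2,
                     n_layers = 1, mlp_hidden = 4, seed = 1)
  model <- e4merInit(cfg, "classify")
  x <- lapply(fs, function(f) matrix(rnorm(3 * 8 * f), 3))
  tok <- channelEmbed(model, x)
  expect_equal(nrow(tok), 3 * 8)                 # B * omega
  expect_equal(ncol(tok), 6 * 2)                 # channels * filters
  enc <- encodeSegments(model, x)
  expect_equal(dim(enc), c(3 * 8, 8))            # (B*N) x d_model
})

test_that("encoding is deterministic in eval mode and batch-independent", {
  model <- e4merInit(tiny_cfg(), "classify")
  x <- rand_x(4)
  e1 <- encodeSegments(model, x)
  e2 <- encodeSegments(model, x)
  expect_identical(e1, e2)
  # permuting the batch permutes outputs identically
  perm <- c(3, 1, 4, 2)
  xp <- lapply(x, function(m) m[perm, , drop = FALSE])
  ep <- encodeSegments(model, xp)
  B <- 4; N <- model$cfg$omega
  for (n in seq_len(N))
    expect_equal(ep[(n - 1) * B + seq_len(B), ],
                 e1[(n - 1) * B + perm, ], tolerance = 1e-12)
})

test_that("classification head emits normalized probabilities", {
  model <- e4merInit(tiny_cfg(), "classify")
  pr <- classifySegments(model, rand_x(5))
  expect_equal(dim(pr), c(5, 2))
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-9)
  # symmetric random inits give probabilities near 1/2 on average
  ps <- vapply(1:8, function(s) {
    m <- e4merInit(e4merConfig(tiny_fs, omega = 6, n_filters = 3, d_model = 8,
                               n_heads = 2, n_layers = 1, mlp_hidden = 5,
                               seed = s), "classify")
    mean(classifySegments(m, rand_x(4, seed = s))[, 1])
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.15)
})

test_that("reconstruction returns native-length channels", {
  model <- e4merInit(tiny_cfg(), "reconstruct")
  x <- rand_x(3)
  out <- reconstructSegments(model, x)
  for (ch in names(tiny_fs))
    expect_equal(dim(out[[ch]]), c(3, 6 * tiny_fs[[ch]]))
  masks <- lapply(x, function(m) matrix(rep(c(TRUE, FALSE),
                                            length.out = length(m)), nrow(m)))
  l <- mpLoss(lapply(x, function(m) m[1, ]),
              lapply(out, function(m) m[1, ]),
              lapply(masks, function(m) m[1, ]))
  expect_true(is.finite(l) && l >= 0)
})

test_that("transform-prediction head has the channels x kinds shape", {
  model <- e4merInit(tiny_cfg(), "transform_predict")
  lg <- predictTransforms(model, rand_x(4))
  expect_equal(dim(lg), c(4, 6, 6))
  expect_gte(tpLoss(matrix(lg[1, , ], 6, 6), rep(1L, 6)), 0)
})

test_that("analytic gradients match finite differences for all heads", {
  B <- 3
  x <- rand_x(B)
  set.seed(31)
  targets <- list(
    classify = list(label = c(1L, 0L, 1L)),
    reconstruct = local({
      masks <- lapply(x, function(m) matrix(runif(length(m)) < 0.3, nrow(m)))
      list(masks = masks, original = x)
    }),
    transform_predict = list(assignment = matrix(sample.int(6, B * 6, TRUE),
                                                 B, 6)))
  for (head in names(targets)) {
    model <- e4merInit(tiny_cfg(), head)
    xi <- x
    if (head == "reconstruct")
      for (ch in names(x)) xi[[ch]][targets[[head]]$masks[[ch]]] <- 0
    lg <- e4mood:::.e4mer_loss_grads(model, xi, targets[[head]],
                                     training = TRUE)
    check <- c("enc.ce_bvp.W", "enc.ce_eda.gamma", "enc.proj.W", "enc.pos",
               "enc.l1.attn.Wq", "enc.l2.attn.Wo", "enc.l1.ln1.g",
               "enc.l2.ffn.W1",
               grep("^head", names(model$params), value = TRUE)[1:2])
    for (nm in check) {
      i <- sample(length(model$params[[nm]]), 1)
      num <- num_grad(model, xi, targets[[head]], nm, i)
      ana <- lg$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4,
                label = paste(head, nm))
    }
  }
})

test_that("linear readout freezes the encoder; fine-tuning does not", {
  pre <- e4merInit(tiny_cfg(), "reconstruct")
  pre$params[["enc.proj.W"]] <- pre$params[["enc.proj.W"]] + 0.05  # "trained"
  segs <- toy_segments(n = 8, omega = 6, fs = tiny_fs, shift = 1.5)
  probe <- segmentBatch(segs, 1:2)$x

  lr <- transferModel(pre, "lr", head_seed = 3)
  expect_true(all(grepl("^head_cls", lr$trainable)))
  expect_false(any(grepl("^head_mp", names(lr$params))))  # pretext head gone
  before <- encodeSegments(lr, probe)
  fit <- trainE4mer(lr, segs, segs[1:2], "classify",
                    trainConfig(batch_size = 4, max_epochs = 2, seed = 5))
  after <- encodeSegments(fit$model, probe)
  expect_identical(unclass(before), unclass(after))       # bit-identical
  expect_identical(fit$model$params[["enc.proj.W"]],
                   lr$params[["enc.proj.W"]])
  # the new head moved
  expect_false(identical(fit$model$params[["head_cls.W1"]],
                         lr$params[["head_cls.W1"]]))

  ft <- transferModel(pre, "ft", head_seed = 3)
  expect_identical(ft$params[["enc.proj.W"]], pre$params[["enc.proj.W"]])
  fit2 <- trainE4mer(ft, segs, segs[1:2], "classify",
                     trainConfig(batch_size = 4, max_epochs = 1, seed = 5))
  expect_false(identical(fit2$model$params[["enc.proj.W"]],
                         ft$params[["enc.proj.W"]]))
})

test_that("training is reproducible and returns the best checkpoint", {
  segs <- toy_segments(n = 12, omega = 6, fs = tiny_fs, shift = 1.2)
  model <- e4merInit(tiny_cfg(), "classify")
  tc <- trainConfig(batch_size = 4, max_epochs = 3, seed = 9)
  f1 <- trainE4mer(model, segs, segs[1:4], "classify", tc)
  f2 <- trainE4mer(model, segs, segs[1:4], "classify", tc)
  expect_identical(f1$history, f2$history)
  expect_lte(f1$best_val, min(f1$history$val_loss))

  # masked prediction improves from the first epoch to the best
  mp <- e4merInit(tiny_cfg(), "reconstruct")
  fm <- trainE4mer(mp, segs, segs[1:4], "mp",
                   trainConfig(batch_size = 4, max_epochs = 4, seed = 9))
  expect_lt(fm$best_val, fm$history$val_loss[1])
  # a tiny tp run fits random labels below chance loss
  tp <- e4merInit(tiny_cfg(), "transform_predict")
  ftp <- trainE4mer(tp, segs, segs[1:4], "tp",
                    trainConfig(batch_size = 4, max_epochs = 4, seed = 9))
  expect_lt(ftp$history$train_loss[4], log(6))
})
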