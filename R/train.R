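#' @include e4mer.R pretext.R
NULL

#' Split unlabeled recordings into train and validation sets
#'
#' Whole recordings are assigned (no recording spans both sets), at random
#' under the seed, in an 85:15 ratio by default.
#'
#' @param recording_ids character vector of recording identifiers.
#' @param val_frac validation fraction (default 0.15).
#' @param seed assignment seed.
#' @return Named character vector (`"train"`/`"val"`) indexed by recording id.
#' @export
splitUnlabeled <- function(recording_ids, val_frac = 0.15, seed = 1) {
  n <- length(recording_ids)
  if (n < 2L) stop("need at least 2 recordings to split")
  n_val <- max(1L, round(val_frac * n))
  .with_seed(seed, {
    val <- sample(recording_ids, n_val)
    stats::setNames(ifelse(recording_ids %in% val, "val", "train"),
                    recording_ids)
  })
}

#' Time-split segments of each recording into train/validation/test
#'
#' Each recording's timeline `[0, duration)` is cut at the 70% and 85% marks
#' (for the default 70:15:15 ratios). A segment belongs to a split only if its
#' whole `[start, start + omega)` span lies inside that split's window;
#' segments straddling a border are dropped, so overlapping motifs never leak
#' across splits.
#'
#' @param segments a [SegmentSet-class].
#' @param ratios numeric length-3 summing to 1 (default `c(.70,.15,.15)`).
#' @param durations named numeric: recording duration (seconds) per session
#'   id; defaults to each recording's last segment end.
#' @return Character vector over segments: `"train"`, `"val"`, `"test"` or
#'   `NA` (dropped at a border).
#' @export
timeSplitTarget <- function(segments, ratios = c(0.70, 0.15, 0.15),
                            durations = NULL) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  info <- segmentInfo(segments)
  omega <- segments@omega
  out <- rep(NA_character_, nrow(info))
  for (sid in unique(info$session_id)) {
    rows <- which(info$session_id == sid)
    dur <- if (!is.null(durations) && sid %in% names(durations))
      durations[[sid]] else max(info$start[rows]) + omega
    c1 <- ratios[1] * dur
    c2 <- (ratios[1] + ratios[2]) * dur
    s <- info$start[rows]; e <- s + omega
    out[rows][e <= c1] <- "train"
    out[rows][s >= c1 & e <= c2] <- "val"
    out[rows][s >= c2 & e <= dur + 1e-9] <- "test"
  }
  out
}

#' Balance classes by rank-pairing recordings
#'
#' Recordings of each class are sorted by segment count and paired
#' rank-to-rank, which minimizes the total absolute within-pair difference;
#' within each pair both recordings keep their first `n = min(count_a,
#' count_b)` segments in temporal order, leaving the classes exactly balanced.
#'
#' @param segments a labeled [SegmentSet-class].
#' @return Logical vector over segments: `TRUE` = retained.
#' @export
balanceClasses <- function(segments) {
  info <- segmentInfo(segments)
  cnt <- table(info$session_id)
  lab <- tapply(info$label, info$session_id, `[`, 1L)
  a_ids <- names(lab)[lab == "acute"]; e_ids <- names(lab)[lab == "euthymia"]
  if (length(a_ids) != length(e_ids))
    stop("class balancing requires equal numbers of recordings per class")
  a_ids <- a_ids[order(-cnt[a_ids])]
  e_ids <- e_ids[order(-cnt[e_ids])]
  keep <- logical(nrow(info))
  for (k in seq_along(a_ids)) {
    n <- min(cnt[[a_ids[k]]], cnt[[e_ids[k]]])
    for (sid in c(a_ids[k], e_ids[k])) {
      rows <- which(info$session_id == sid)
      rows <- rows[order(info$start[rows])]
      keep[rows[seq_len(n)]] <- TRUE
    }
  }
  keep
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' One [schedulerStep()] call per epoch: an improvement in the validation
#' metric resets the staleness counter; `patience` consecutive stale epochs
#' multiply the learning rate by `factor` (and reset the counter); when a
#' further reduction beyond `max_reductions` would be needed, training stops.
#'
#' @param lr initial learning rate.
#' @param patience stale epochs tolerated before acting (default 10).
#' @param factor learning-rate multiplier (default 0.3).
#' @param max_reductions reductions allowed before termination (default 2).
#' @return A scheduler state list.
#' @export
schedulerInit <- function(lr, patience = 10, factor = 0.3,
                          max_reductions = 2) {
  list(best = Inf, stale = 0L, n_reductions = 0L, lr = lr,
       patience = patience, factor = factor, max_reductions = max_reductions)
}

#' @rdname schedulerInit
#' @param state scheduler state.
#' @param val validation metric (lower is better).
#' @return Updated state with `$action` one of `"continue"`, `"reduce"`,
#'   `"stop"`, and `$improved`.
#' @export
schedulerStep <- function(state, val) {
  state$improved <- val < state$best
  if (state$improved) {
    state$best <- val
    state$stale <- 0L
    state$action <- "continue"
    return(state)
  }
  state$stale <- state$stale + 1L
  if (state$stale >= state$patience) {
    if (state$n_reductions >= state$max_reductions) {
      state$action <- "stop"
    } else {
      state$lr <- state$lr * state$factor
      state$n_reductions <- state$n_reductions + 1L
      state$stale <- 0L
      state$action <- "reduce"
    }
  } else state$action <- "continue"
  state
}

#' Training configuration
#'
#' @param lr initial learning rate (AdamW).
#' @param batch_size minibatch size (the full-scale default is 256; scale
#'   down for small synthetic runs).
#' @param max_epochs epoch cap (default 300).
#' @param patience,lr_factor,max_reductions plateau-scheduler parameters.
#' @param weight_decay decoupled weight decay.
#' @param seed seed for shuffling and pretext sampling.
#' @param spec a [maskSpec()] for masked prediction.
#' @param verbose print per-epoch losses.
#' @return A list of class `train_config`.
#' @export
trainConfig <- function(lr = 1e-3, batch_size = 256, max_epochs = 300,
                        patience = 10, lr_factor = 0.3, max_reductions = 2,
                        weight_decay = 0.01, seed = 1, spec = maskSpec(),
                        verbose = FALSE) {
  structure(list(lr = lr, batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, lr_factor = lr_factor,
                 max_reductions = max_reductions,
                 weight_decay = weight_decay, seed = seed, spec = spec,
                 verbose = verbose),
            class = "train_config")
}

.make_target <- function(task, batch, model, spec) {
  if (task == "classify") {
    list(x = batch$x, target = list(label = batch$label))
  } else if (task == "mp") {
    masks <- list(); xin <- batch$x
    for (ch in names(model$cfg$fs)) {
      L <- ncol(batch$x[[ch]])
      mk <- t(vapply(seq_len(nrow(batch$x[[ch]])), function(i)
        sampleMask(L, spec, model$cfg$fs[[ch]]), logical(L)))
      masks[[ch]] <- mk
      xin[[ch]] <- batch$x[[ch]] * !mk
    }
    list(x = xin, target = list(masks = masks, original = batch$x))
  } else {
    C <- length(model$cfg$fs)
    B <- nrow(batch$x[[1L]])
    assign_mat <- matrix(sampleTransforms(B * C), B, C)
    xin <- batch$x
    for (ci in seq_len(C)) {
      ch <- names(model$cfg$fs)[ci]
      for (b in seq_len(B))
        xin[[ch]][b, ] <- applyTransform(batch$x[[ch]][b, ],
                                         assign_mat[b, ci])
    }
    list(x = xin, target = list(assignment = assign_mat))
  }
}

.eval_loss <- function(model, task, prepared) {
  if (task == "classify") {
    pr <- classifySegments(model, prepared$x)
    y <- prepared$target$label
    eps <- 1e-12
    -mean(y * log(pr[, 1] + eps) + (1 - y) * log(pr[, 2] + eps))
  } else if (task == "mp") {
    xhat <- reconstructSegments(model, prepared$x)
    sq <- 0; m <- 0
    for (ch in names(xhat)) {
      k <- prepared$target$masks[[ch]]
      sq <- sq + sum(((xhat[[ch]] - prepared$target$original[[ch]]) * k)^2)
      m <- m + sum(k)
    }
    sqrt(sq / m)
  } else {
    lg <- predictTransforms(model, prepared$x)
    B <- dim(lg)[1L]
    mean(vapply(seq_len(B), function(b)
      tpLoss(matrix(lg[b, , ], dim(lg)[2L], 6L),
             prepared$target$assignment[b, ]), numeric(1)))
  }
}

#' Train an E4mer model
#'
#' Minibatch AdamW training with the reduce-on-plateau scheduler, for the
#' supervised target task (`task = "classify"`, BCE loss), masked prediction
#' (`"mp"`, masked RMSE) or transformation prediction (`"tp"`, channel-average
#' cross-entropy). The best-validation checkpoint is returned; training is
#' fully seeded and single-threaded deterministic. Only `model$trainable`
#' parameters are updated, so linear readout respects the freeze contract.
#'
#' @param model from [e4merInit()] or [transferModel()].
#' @param train,val standardized [SegmentSet-class] collections.
#' @param task `"classify"`, `"mp"` or `"tp"`.
#' @param cfg a [trainConfig()].
#' @return List: `model` (best checkpoint), `history` (per-epoch data.frame),
#'   `best_val`, `stopped_epoch`.
#' @export
trainE4mer <- function(model, train, val, task = c("classify", "mp", "tp"),
                       cfg = trainConfig()) {
  task <- match.arg(task)
  stopifnot(inherits(cfg, "train_config"))
  if (nSegments(train) == 0L) stop("empty training set")
  need_head <- c(classify = "classify", mp = "reconstruct",
                 tp = "transform_predict")[[task]]
  if (model$head != need_head)
    stop(sprintf("model head '%s' does not match task '%s'", model$head, task))

  .with_seed(cfg$seed, {
    opt <- adamwInit(model$params, lr = cfg$lr,
                     weight_decay = cfg$weight_decay)
    sched <- schedulerInit(cfg$lr, cfg$patience, cfg$lr_factor,
                           cfg$max_reductions)
    n <- nSegments(train)
    val_batch <- if (nSegments(val) > 0L)
      .make_target(task, segmentBatch(val), model, cfg$spec) else NULL
    best <- list(params = model$params, bn = model$bn, val = Inf)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric(), lr = numeric(),
                       event = character())
    for (epoch in seq_len(cfg$max_epochs)) {
      opt$lr <- sched$lr
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (s0 in seq(1L, n, by = cfg$batch_size)) {
        bidx <- idx[s0:min(s0 + cfg$batch_size - 1L, n)]
        if (length(bidx) < 2L) next     # batch norm needs >= 2 rows
        batch <- segmentBatch(train, bidx)
        prep <- .make_target(task, batch, model, cfg$spec)
        lg <- .e4mer_loss_grads(model, prep$x, prep$target, training = TRUE)
        model <- lg$model
        st <- adamwStep(model$params, lg$grads, opt, model$trainable)
        model$params <- st$params; opt <- st$opt
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      }
      vl <- if (!is.null(val_batch)) .eval_loss(model, task, val_batch)
        else ep_loss / max(nb, 1L)
      sched <- schedulerStep(sched, vl)
      if (sched$improved) best <- list(params = model$params, bn = model$bn,
                                       val = vl)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = ep_loss / max(nb, 1L),
                                     val_loss = vl, lr = sched$lr,
                                     event = sched$action))
      if (cfg$verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e  %s",
                        epoch, ep_loss / max(nb, 1L), vl, sched$lr,
                        sched$action))
      if (sched$action == "stop") break
    }
    model$params <- best$params
    model$bn <- best$bn
    list(model = model, history = hist, best_val = best$val,
         stopped_epoch = nrow(hist))
  })
}

#' Segment-level class probabilities
#'
#' @param model a classification-head E4mer.
#' @param segments standardized [SegmentSet-class].
#' @param batch_size forward batch size.
#' @return Numeric vector of P(acute) per segment.
#' @export
predictProbs <- function(model, segments, batch_size = 64) {
  n <- nSegments(segments)
  out <- numeric(n)
  for (s0 in seq(1L, n, by = batch_size)) {
    idx <- s0:min(s0 + batch_size - 1L, n)
    batch <- segmentBatch(segments, idx)
    out[idx] <- classifySegments(model, batch$x)[, 1L]
  }
  out
}
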