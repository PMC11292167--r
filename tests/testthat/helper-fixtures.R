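# Fixture builders and independent reference implementations used as oracles.

# Build a session from per-second scalar patterns: eda/temp are repeated to
# their sampling rates; acceleration is generated from a per-second arm
# elevation schedule (degrees) with azimuth 0, so angle recovery is exact.
make_session <- function(eda_per_s, temp_per_s = rep(33, length(eda_per_s)),
                         angle_per_s = rep(0, length(eda_per_s)),
                         fs_eda = 4, fs_temp = 1, fs_acc = 32,
                         id = "tst", label = NA_character_, t0 = 1585000000) {
  D <- length(eda_per_s)
  th <- rep(angle_per_s * pi / 180, each = fs_acc)
  E4Session(id, id, "testds",
            channels = list(
              ChannelSeries("acc_x", cos(th), fs_acc, t0),
              ChannelSeries("acc_y", rep(0, D * fs_acc), fs_acc, t0),
              ChannelSeries("acc_z", sin(th), fs_acc, t0),
              ChannelSeries("bvp", sin(2 * pi * 1.2 * seq_len(D * 64) / 64),
                            64, t0),
              ChannelSeries("eda", rep(eda_per_s, each = fs_eda), fs_eda, t0),
              ChannelSeries("temp", rep(temp_per_s, each = fs_temp), fs_temp,
                            t0)),
            label = label)
}

# Brute-force per-second timeline: a literal, loop-based restatement of the
# three rules, independent of the package implementation.
oracle_timeline <- function(session, eda_min = 0.05, eda_max = 100,
                            temp_lo = 30, temp_hi = 40, min_run = 300,
                            angle_thr = 5, min_sleep = 300) {
  chs <- session@channels
  D <- floor(min(sapply(chs, function(ch) length(ch@values) / ch@fs)))
  eda <- chs$eda; temp <- chs$temp
  off <- logical(D)
  for (s in 0:(D - 1)) {
    ei <- which(floor((seq_along(eda@values) - 1) / eda@fs) == s)
    ti <- which(floor((seq_along(temp@values) - 1) / temp@fs) == s)
    ev <- eda@values[ei]; tv <- temp@values[ti]
    off[s + 1] <- any(ev < eda_min | ev > eda_max, na.rm = TRUE) ||
      any(tv < temp_lo | tv > temp_hi, na.rm = TRUE)
  }
  # minimum wear-run rule, by explicit scan
  s <- 1
  while (s <= D) {
    if (!off[s]) {
      e <- s
      while (e < D && !off[e + 1]) e <- e + 1
      if (e - s + 1 < min_run) off[s:e] <- TRUE
      s <- e + 1
    } else s <- s + 1
  }
  # arm angle on 5 s epochs
  fs <- chs$acc_x@fs
  n_ep <- floor(D / 5)
  ang <- numeric(n_ep)
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1) * 5 * fs + 1):(e * 5 * fs)
    mx <- median(chs$acc_x@values[idx]); my <- median(chs$acc_y@values[idx])
    mz <- median(chs$acc_z@values[idx])
    ang[e] <- if (sqrt(mx^2 + my^2) == 0 && mz == 0) 0
      else atan2(mz, sqrt(mx^2 + my^2)) * 180 / pi
  }
  st <- ifelse(off, "off_body", "wake")
  ep_on <- sapply(seq_len(n_ep), function(e)
    !any(off[((e - 1) * 5 + 1):min(e * 5, D)]))
  e <- 1
  while (e <= n_ep) {
    if (!ep_on[e]) { e <- e + 1; next }
    # extend a maximal run of on-body epochs with successive changes <= thr
    r <- e
    while (r < n_ep && ep_on[r + 1] && abs(ang[r + 1] - ang[r]) <= angle_thr)
      r <- r + 1
    if ((r - e + 1) * 5 >= min_sleep) {
      secs <- ((e - 1) * 5 + 1):min(r * 5, D)
      st[secs][!off[secs]] <- "sleep"
    }
    e <- r + 1
  }
  st
}

# a small standardized SegmentSet with controllable labels for model tests
toy_segments <- function(n = 8, omega = 4,
                         fs = c(acc_x = 4, acc_y = 4, acc_z = 4, bvp = 8,
                                eda = 2, temp = 1),
                         labels = rep(c("acute", "euthymia"), length.out = n),
                         subjects = rep(sprintf("S%d", 1:2), length.out = n),
                         shift = 1, seed = 1) {
  set.seed(seed)
  data <- lapply(seq_len(n), function(i) {
    mu <- if (labels[i] == "acute") shift else 0
    lapply(fs, function(f) rnorm(omega * f, mean = mu))
  })
  info <- data.frame(session_id = subjects, subject_id = subjects,
                     dataset_id = "toy", start = seq_len(n) * omega,
                     label = labels, stringsAsFactors = FALSE)
  SegmentSet(data, info, omega, fs, standardized = TRUE)
}

# numeric central difference for one coordinate of one parameter
num_grad <- function(model, x, target, nm, i, eps = 1e-5) {
  mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
  mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
  lp <- e4mood:::.e4mer_loss_grads(mp, x, target, training = TRUE)$loss
  lm <- e4mood:::.e4mer_loss_grads(mm, x, target, training = TRUE)$loss
  (lp - lm) / (2 * eps)
}
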