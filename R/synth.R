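#' @include AllClasses.R
NULL

.ar1 <- function(n, sd, phi = 0.9) {
  if (n == 0L) return(numeric(0))
  as.numeric(stats::filter(stats::rnorm(n, 0, sd), phi, method = "recursive"))
}

# run code with a derived, restored RNG state so generation is reproducible
# without clobbering the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the simulated study conditions: cohort size and class balance,
#' session length, hourly wear probability, the sleep window, the per-channel
#' two-class physiological effect, noise levels, and the master seed (which
#' fully determines the output).
#'
#' The signal model is baseline + circadian sinusoid + AR(1) noise per
#' channel; acceleration is a gravity orientation vector (constant during
#' sleep, re-oriented roughly once a minute during wake) plus movement noise;
#' BVP is an amplitude-modulated oscillation at the instantaneous pulse rate,
#' from which the IBI event series is derived. The acute class shifts mean EDA
#' by `eda_shift` µS, scales wake movement noise by `activity_scale`, and
#' shifts heart rate by `hr_shift` bpm.
#'
#' @param n_subjects number of subjects (one session each).
#' @param class_ratio fraction of subjects labeled `acute` (in `[0,1]`).
#' @param session_hours session duration in hours.
#' @param wear_prob probability that a given hour is worn.
#' @param sleep_window `c(start_h, end_h)` session hours spent asleep (worn
#'   hours inside the window are sleep); `NULL` for no sleep.
#' @param effect list: `eda_shift` (µS), `activity_scale` (unitless multiplier
#'   on wake movement noise), `hr_shift` (bpm) applied to the acute class.
#' @param noise_sd list of per-channel innovation SDs: `eda` (µS),
#'   `temp` (°C), `acc` (g), `bvp` (a.u.), `hr` (bpm).
#' @param dataset_id dataset identifier stamped on generated sessions.
#' @param seed master seed; `(cfg, seed)` determines the cohort bitwise.
#' @return A validated list of class `synth_config`.
#' @export
synthConfig <- function(n_subjects = 10, class_ratio = 0.5, session_hours = 8,
                        wear_prob = 0.9, sleep_window = c(2, 6),
                        effect = list(eda_shift = 0.5, activity_scale = 1.25,
                                      hr_shift = 5),
                        noise_sd = list(eda = 0.02, temp = 0.05, acc = 0.05,
                                        bvp = 0.1, hr = 1),
                        dataset_id = "synth", seed = 1) {
  stopifnot(n_subjects >= 1, class_ratio >= 0, class_ratio <= 1,
            session_hours > 0, wear_prob >= 0, wear_prob <= 1)
  if (!is.null(sleep_window))
    stopifnot(length(sleep_window) == 2, sleep_window[1] <= sleep_window[2])
  cfg <- list(n_subjects = n_subjects, class_ratio = class_ratio,
              session_hours = session_hours, wear_prob = wear_prob,
              sleep_window = sleep_window, effect = effect,
              noise_sd = noise_sd, dataset_id = dataset_id, seed = seed)
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate one wristband session
#'
#' Generates an [E4Session-class] at the native channel rates (acceleration
#' 32 Hz, BVP 64 Hz, EDA 4 Hz, TEMP and HR 1 Hz) with the wear/nonwear,
#' sleep/wake and class structure requested by the config. Nonwear bouts have
#' EDA below 0.05 µS and out-of-range temperature; sleep bouts have a
#' near-constant arm angle; wake re-orients the arm about once a minute.
#' The ground-truth per-second status is attached and retrievable with
#' [trueStatus()].
#'
#' @param cfg a [synthConfig()].
#' @param subject_index 1-based subject index (seeds the subject's stream).
#' @param label `"acute"`, `"euthymia"` or `NA` (unlabeled).
#' @return An [E4Session-class].
#' @export
simulateSession <- function(cfg, subject_index, label = NA_character_) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_seed(cfg$seed * 10000L + subject_index, {
    H <- cfg$session_hours
    D <- as.integer(round(H * 3600))
    t0 <- 1585000000 + subject_index * 100000
    acute <- identical(label, "acute")

    worn_h <- stats::runif(ceiling(H)) < cfg$wear_prob
    hour_of <- pmin(floor((0:(D - 1)) / 3600) + 1L, ceiling(H))
    worn <- worn_h[hour_of]
    asleep <- rep(FALSE, D)
    if (!is.null(cfg$sleep_window)) {
      hr_frac <- (0:(D - 1)) / 3600
      asleep <- worn & hr_frac >= cfg$sleep_window[1] &
        hr_frac < cfg$sleep_window[2]
    }
    st <- ifelse(!worn, "off_body", ifelse(asleep, "sleep", "wake"))

    ## --- acceleration: orientation + movement noise ------------------------
    # per-second elevation/azimuth; wake jumps ~1/min, sleep/nonwear constant
    theta <- numeric(D); phi <- numeric(D)
    cur_th <- stats::runif(1, -60, 60); cur_ph <- stats::runif(1, -180, 180)
    sleep_th <- stats::runif(1, -60, 60); sleep_ph <- stats::runif(1, -180, 180)
    next_jump <- 0
    for (s in seq_len(D)) {
      if (st[s] == "wake" && (s - 1) >= next_jump) {
        cur_th <- cur_th + sample(c(-1, 1), 1) * stats::runif(1, 12, 45)
        cur_th <- ((cur_th + 90) %% 180) - 90
        cur_ph <- stats::runif(1, -180, 180)
        next_jump <- (s - 1) + stats::runif(1, 30, 75)
      }
      if (st[s] == "sleep") { theta[s] <- sleep_th; phi[s] <- sleep_ph }
      else { theta[s] <- cur_th; phi[s] <- cur_ph }
    }
    fs_acc <- 32L
    th_s <- rep(theta, each = fs_acc) * pi / 180
    ph_s <- rep(phi, each = fs_acc) * pi / 180
    act_sd <- cfg$noise_sd$acc *
      ifelse(rep(st, each = fs_acc) == "wake",
             if (acute) cfg$effect$activity_scale else 1,
             ifelse(rep(st, each = fs_acc) == "sleep", 0.1, 0.05))
    n_acc <- D * fs_acc
    acc_x <- cos(th_s) * cos(ph_s) + stats::rnorm(n_acc, 0, act_sd)
    acc_y <- cos(th_s) * sin(ph_s) + stats::rnorm(n_acc, 0, act_sd)
    acc_z <- sin(th_s) + stats::rnorm(n_acc, 0, act_sd)

    ## --- EDA (4 Hz) --------------------------------------------------------
    fs_eda <- 4L; n_eda <- D * fs_eda
    tt <- (0:(n_eda - 1)) / fs_eda
    base <- ifelse(rep(st, each = fs_eda) == "sleep", 0.22, 0.30) +
      (if (acute) cfg$effect$eda_shift else 0)
    eda <- base + 0.05 * sin(2 * pi * tt / 86400 + stats::runif(1, 0, 2 * pi)) +
      .ar1(n_eda, cfg$noise_sd$eda, 0.95)
    eda <- pmin(pmax(eda, 0.08), 90)             # sensor floor while worn
    off_s <- rep(st, each = fs_eda) == "off_body"
    eda[off_s] <- pmin(pmax(0.01 + stats::rnorm(sum(off_s), 0, 0.005), 0), 0.04)

    ## --- TEMP (1 Hz) -------------------------------------------------------
    temp <- 33 + 0.5 * sin(2 * pi * (0:(D - 1)) / 86400) +
      .ar1(D, cfg$noise_sd$temp, 0.95)
    temp <- pmin(pmax(temp, 30.5), 39.5)
    temp[st == "off_body"] <- 26 + .ar1(sum(st == "off_body"), 0.2, 0.9)

    ## --- HR (1 Hz) and BVP (64 Hz) ------------------------------------------
    hr <- 70 + (if (acute) cfg$effect$hr_shift else 0) - 8 * (st == "sleep") +
      3 * sin(2 * pi * (0:(D - 1)) / 86400) + .ar1(D, cfg$noise_sd$hr, 0.9)
    hr <- pmax(hr, 40)
    fs_bvp <- 64L
    f_inst <- rep(hr, each = fs_bvp) / 60
    phase <- cumsum(2 * pi * f_inst / fs_bvp)
    amp <- 1 + 0.2 * sin(2 * pi * (0:(D * fs_bvp - 1)) / (fs_bvp * 300))
    bvp <- amp * sin(phase) + stats::rnorm(D * fs_bvp, 0, cfg$noise_sd$bvp)

    ## --- IBI events from the pulse rate -------------------------------------
    ev <- numeric(0); iv <- numeric(0); t_e <- 60 / hr[1]
    while (t_e < D) {
      h <- hr[min(D, floor(t_e) + 1L)]
      ev <- c(ev, t_e); iv <- c(iv, 60 / h)
      t_e <- t_e + 60 / h
    }

    sid <- sprintf("%s_S%02d", cfg$dataset_id, subject_index)
    sess <- E4Session(session_id = sid, subject_id = sid,
                      dataset_id = cfg$dataset_id, label = label,
                      channels = list(
                        ChannelSeries("acc_x", acc_x, fs_acc, t0),
                        ChannelSeries("acc_y", acc_y, fs_acc, t0),
                        ChannelSeries("acc_z", acc_z, fs_acc, t0),
                        ChannelSeries("bvp", bvp, fs_bvp, t0),
                        ChannelSeries("eda", eda, fs_eda, t0),
                        ChannelSeries("temp", temp, 1, t0),
                        ChannelSeries("hr", hr, 1, t0)),
                      ibi = IBISeries(ev, iv))
    attr(sess, "true_status") <- st
    sess
  })
}

#' Ground-truth status of a simulated session
#'
#' @param session an [E4Session-class] produced by [simulateSession()].
#' @return Character vector of per-second true statuses, or `NULL` for
#'   sessions that did not come from the generator.
#' @export
trueStatus <- function(session) attr(session, "true_status")

#' Simulate a cohort of sessions
#'
#' One session per subject; the first `round(n_subjects * class_ratio)`
#' subjects are labeled `acute`, the rest `euthymia` (all `NA` when
#' `labelled = FALSE`). Fully reproducible under the config seed.
#'
#' @param cfg a [synthConfig()].
#' @param labelled generate class labels (default) or an unlabeled cohort.
#' @return A list of [E4Session-class] objects.
#' @export
simulateCohort <- function(cfg, labelled = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_subjects
  if (labelled) {
    if (n < 2 && cfg$class_ratio > 0 && cfg$class_ratio < 1)
      stop("both classes requested but fewer than 2 subjects")
    k <- round(n * cfg$class_ratio)
    labels <- c(rep("acute", k), rep("euthymia", n - k))
  } else labels <- rep(NA_character_, n)
  lapply(seq_len(n), function(i) simulateSession(cfg, i, labels[i]))
}
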