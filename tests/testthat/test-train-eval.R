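test_that("unlabeled split partitions whole recordings 85:15", {
  ids <- sprintf("R%02d", 1:20)
  sp <- splitUnlabeled(ids, seed = 3)
  expect_equal(sum(sp == "train"), 17)
  expect_equal(sum(sp == "val"), 3)
  expect_setequal(names(sp), ids)
  expect_identical(sp, splitUnlabeled(ids, seed = 3))
  expect_false(identical(sp, splitUnlabeled(ids, seed = 4)))
  expect_error(splitUnlabeled("one"), "at least 2")
})

mk_info_set <- function(starts, sids, labels = NA_character_, omega = 512) {
  fs <- c(acc_x = 1, acc_y = 1, acc_z = 1, bvp = 1, eda = 1, temp = 1)
  data <- lapply(starts, function(s) lapply(fs, function(f) rep(0, omega)))
  info <- data.frame(session_id = sids, subject_id = sids, dataset_id = "d",
                     start = starts,
                     label = rep(labels, length.out = length(starts)),
                     stringsAsFactors = FALSE)
  SegmentSet(data, info, omega, fs)
}

test_that("time split confines overlapping windows to one split", {
  omega <- 512; step <- 128; dur <- 5120
  starts <- seq(0, dur - omega, by = step)
  segs <- mk_info_set(starts, "rec1", omega = omega)
  sp <- timeSplitTarget(segs, durations = c(rec1 = dur))
  # brute-force interval check
  c1 <- 0.7 * dur; c2 <- 0.85 * dur
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- s + omega
    ref <- if (e <= c1) "train" else if (s >= c1 && e <= c2) "val"
      else if (s >= c2) "test" else NA_character_
    expect_identical(sp[i], ref)
  }
  expect_true(any(is.na(sp)))           # border stragglers are dropped

  # with step = omega and borders aligned to window multiples, nothing drops
  dur2 <- 10240
  starts2 <- seq(0, dur2 - omega, by = omega)
  segs2 <- mk_info_set(starts2, "rec2", omega = omega)
  sp2 <- timeSplitTarget(segs2, durations = c(rec2 = dur2))
  expect_false(any(is.na(sp2)))
  expect_equal(unname(table(sp2)[c("train", "val", "test")]),
               c(14L, 3L, 3L), ignore_attr = TRUE)

  expect_error(timeSplitTarget(segs, ratios = c(0.7, 0.2, 0.2)), "sum to 1")
})

test_that("rank pairing balances classes and keeps first-n segments", {
  # class A recordings with 10 and 4 segments; class B with 8 and 5
  starts <- c(seq_len(10), seq_len(4), seq_len(8), seq_len(5)) * 10
  sids <- rep(c("a1", "a2", "b1", "b2"), c(10, 4, 8, 5))
  labels <- rep(c("acute", "acute", "euthymia", "euthymia"), c(10, 4, 8, 5))
  segs <- mk_info_set(starts, sids, omega = 8)
  segs@info$label <- labels
  keep <- balanceClasses(segs)
  info <- segmentInfo(segs)
  kept <- table(info$session_id[keep])
  # sorted pairing: (10,8) and (4,5) -> keep 8+4 per class
  expect_equal(unname(kept[c("a1", "a2", "b1", "b2")]), c(8L, 4L, 8L, 4L),
               ignore_attr = TRUE)
  expect_equal(sum(info$label[keep] == "acute"),
               sum(info$label[keep] == "euthymia"))
  # first n in temporal order are the ones retained
  a1_starts <- sort(info$start[info$session_id == "a1"])[1:8]
  expect_setequal(info$start[keep & info$session_id == "a1"], a1_starts)

  # identical counts: nothing dropped
  segs2 <- mk_info_set(rep(1:4, 2) * 10, rep(c("x", "y"), each = 4),
                       omega = 8)
  segs2@info$label <- rep(c("acute", "euthymia"), each = 4)
  expect_true(all(balanceClasses(segs2)))
})

test_that("plateau scheduler reduces by 0.3 and stops after two reductions", {
  st <- schedulerInit(1e-3)
  st <- schedulerStep(st, 1.0)          # improvement (best was Inf)
  for (i in 1:9) st <- schedulerStep(st, 2.0)
  expect_equal(st$action, "continue")   # 9 stale epochs: not yet
  st9 <- schedulerStep(st, 0.5)         # improvement at epoch 9 resets
  expect_equal(st9$stale, 0L)
  expect_equal(st9$lr, 1e-3)

  st <- schedulerStep(st, 2.0)          # 10th stale epoch
  expect_equal(st$action, "reduce")
  expect_equal(st$lr, 3e-4)
  expect_equal(st$n_reductions, 1L)
  for (i in 1:10) st <- schedulerStep(st, 2.0)
  expect_equal(st$lr, 9e-5)
  expect_equal(st$n_reductions, 2L)
  for (i in 1:9) st <- schedulerStep(st, 2.0)
  expect_equal(st$action, "continue")
  st <- schedulerStep(st, 2.0)          # a third reduction would be needed
  expect_equal(st$action, "stop")
})

test_that("majority-vote metrics follow their definitions", {
  probs <- c(0.9, 0.8, 0.6, 0.2, 0.3)
  labels <- rep("acute", 5)
  ev <- evaluateClassifier(probs, labels, rep("s1", 5))
  expect_equal(ev$acc_segment, 60)          # 3 of 5 over 0.5
  expect_equal(ev$acc_subject, 100)         # majority vote correct
  expect_equal(ev$per_subject$mean_prob, mean(probs))

  ev2 <- evaluateClassifier(c(0.9, 0.2, 0.7), c("acute", "acute", "acute"),
                            rep("s", 3))
  expect_equal(ev2$per_subject$mean_prob, 0.6)

  # all segments correct -> both accuracies 100
  ev3 <- evaluateClassifier(c(0.9, 0.1, 0.8, 0.2),
                            c("acute", "euthymia", "acute", "euthymia"),
                            c("s1", "s2", "s1", "s2"))
  expect_equal(ev3$acc_segment, 100)
  expect_equal(ev3$acc_subject, 100)
  expect_equal(unname(ev3$segment["auroc"]), 1)

  # tie in votes broken by the subject-level mean probability
  ev4 <- evaluateClassifier(c(0.9, 0.4), c("acute", "acute"), c("s", "s"))
  expect_equal(ev4$acc_subject, 100)        # vote 1-1, mean prob 0.65
  ev5 <- evaluateClassifier(c(0.55, 0.1), c("acute", "acute"), c("s", "s"))
  expect_equal(ev5$acc_subject, 0)          # vote 1-1, mean prob 0.325

  # a subject is correct iff its correct-vote fraction exceeds 1/2
  set.seed(8)
  probs <- runif(60); labels <- sample(c("acute", "euthymia"), 60, TRUE)
  sid <- sample(sprintf("s%d", 1:7), 60, TRUE)
  ev6 <- evaluateClassifier(probs, labels, sid)
  with(ev6$per_subject, {
    expect_true(all(pred[correct_frac > 0.5] == label[correct_frac > 0.5]))
    expect_true(all(pred[correct_frac < 0.5] != label[correct_frac < 0.5]))
  })
})

test_that("identical models compare as a perfect null", {
  set.seed(3)
  p <- runif(40); y <- sample(c("acute", "euthymia"), 40, TRUE)
  sid <- rep(sprintf("s%d", 1:8), each = 5)
  cm <- compareModels(p, p, y, sid)
  expect_equal(cm$mean_diff, 0)
  expect_equal(cm$t_segment$p_bonf, 1)
  expect_equal(cm$t_subject$p_bonf, 1)
  expect_equal(cm$lme$p_bonf, 1)
  expect_true(cm$t_segment$degenerate)

  # constant nonzero difference is flagged degenerate, not given a p value
  cm2 <- compareModels(p, pmin(1, p + 0.1), y, sid)
  expect_true(is.finite(cm2$mean_diff))
  expect_error(compareModels(p, p[-1], y, sid), "unpaired")
})

test_that("the mixed model recovers a simulated population mean difference", {
  # subject-clustered differences: d_ij = mu + b_i + e_ij
  mu <- 0.06
  cover <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    n_sub <- 12; n_seg <- 12
    b <- rnorm(n_sub, 0, 0.05)
    sid <- rep(sprintf("s%d", 1:n_sub), each = n_seg)
    d <- mu + rep(b, each = n_seg) + rnorm(n_sub * n_seg, 0, 0.08)
    fit <- suppressMessages(
      lmerTest::lmer(d ~ 1 + (1 | g), data = data.frame(d = d, g = sid)))
    cf <- coef(summary(fit))     # Satterthwaite t-interval for the intercept
    half <- qt(0.975, cf[1, "df"]) * cf[1, "Std. Error"]
    if (cf[1, "Estimate"] - half <= mu && mu <= cf[1, "Estimate"] + half)
      cover <- cover + 1
  }
  expect_gte(cover / n_rep, 0.85)   # nominal 95% Wald coverage

  # and compareModels' LME intercept sits near the simulated mean
  set.seed(11)
  n_sub <- 10; n_seg <- 20
  sid <- rep(sprintf("s%d", 1:n_sub), each = n_seg)
  y <- rep("acute", n_sub * n_seg)
  pb <- runif(n_sub * n_seg, 0.3, 0.7)
  d <- mu + rep(rnorm(n_sub, 0, 0.04), each = n_seg) +
    rnorm(n_sub * n_seg, 0, 0.06)
  cm <- compareModels(pmin(0.99, pb + d), pb, y, sid)
  expect_lt(abs(cm$lme$estimate - mu), 0.05)
  expect_lt(cm$lme$p_bonf, 0.05)
})

test_that("pearsonCorr guards its preconditions", {
  x <- 1:10
  expect_equal(pearsonCorr(x, 2 * x + 1), 1)
  expect_error(pearsonCorr(1:3, 1:4), "equal length")
  expect_error(pearsonCorr(1:2, 2:3), "at least 3")
  expect_error(pearsonCorr(rep(1, 5), 1:5), "zero variance")
})

test_that("ablation selection is stratified and the harness reports deltas", {
  ds <- rep(c("A", "B", "C"), c(10, 4, 2))
  keep <- selectAblation(ds, "downsample", ratio = 0.5, seed = 2)
  expect_equal(sum(keep[ds == "A"]), 5)
  expect_equal(sum(keep[ds == "B"]), 2)
  expect_equal(sum(keep[ds == "C"]), 1)
  expect_false(any(selectAblation(ds, "downsample", ratio = 0)))
  # at least one recording per retained dataset even at tiny ratios
  expect_true(all(tapply(selectAblation(ds, "downsample", ratio = 0.01),
                         ds, sum) >= 1))
  loo <- selectAblation(ds, "leave_one_out", dataset = "B")
  expect_identical(loo, ds != "B")
  expect_error(selectAblation(ds, "leave_one_out", dataset = "Z"), "unknown")

  # mock pipeline: accuracy proportional to pretraining volume
  runner <- function(recs) list(acc_segment = 50 + length(recs),
                                acc_subject = 50 + 2 * length(recs))
  ref <- runner(as.list(seq_along(ds)))
  ab <- ablateCollection(as.list(seq_along(ds)), ds, runner, reference = ref,
                         mode = "downsample", ratio = 1)
  expect_equal(ab$delta_acc_segment, 0)      # full ratio reuses the reference
  ab2 <- ablateCollection(as.list(seq_along(ds)), ds, runner, reference = ref,
                          mode = "leave_one_out", dataset = "A")
  expect_equal(ab2$delta_acc_segment, -10)   # 10 recordings removed
  expect_equal(ab2$delta_acc_subject, -20)
  expect_equal(sum(ab2$kept), 6)
})

test_that("bundled ablation tables load with the documented columns", {
  ds <- ablationReference("downsampling")
  expect_equal(nrow(ds), 5)
  expect_true(all(c("resampling_ratio", "acc_segment_diff",
                    "acc_subject_diff") %in% names(ds)))
  lo <- ablationReference("leave_one_out")
  expect_equal(nrow(lo), 12)
  expect_true(all(c("relative_size", "acc_segment_diff") %in% names(lo)))
})
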