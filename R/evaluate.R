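#' @include train.R
NULL

.prf <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0))
    2 * precision * recall / (precision + recall) else NA_real_
  c(precision = precision, recall = recall, f1 = f1)
}

.auroc <- function(truth, prob) {
  if (length(unique(truth)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                 levels = c(0, 1), direction = "<")))
}

#' Segment- and subject-level evaluation
#'
#' Segment accuracy is the fraction of correctly classified segments (a
#' segment is called acute when `P(acute) > 0.5`). A subject's predicted class
#' is the majority vote over that subject's segments — a subject is correct
#' iff its correct-vote fraction exceeds 0.5, with exact ties broken by the
#' subject-level probability (the mean of the subject's segment
#' probabilities). Precision/recall/F1 and AUROC are reported at both levels,
#' treating `acute` as the positive class.
#'
#' @param probs per-segment P(acute).
#' @param labels per-segment true labels (`"acute"`/`"euthymia"` or 1/0).
#' @param subject_ids per-segment subject identifiers.
#' @return A list (informally, the evaluation report): `acc_segment`,
#'   `acc_subject` (both in percent), `segment` and `subject` metric vectors,
#'   `per_subject` data.frame with vote fractions and mean probabilities.
#' @export
evaluateClassifier <- function(probs, labels, subject_ids) {
  y <- if (is.numeric(labels)) as.integer(labels)
    else as.integer(labels == "acute")
  stopifnot(length(probs) == length(y), length(y) == length(subject_ids))
  if (any(table(subject_ids) == 0L)) stop("subject with zero segments")
  pred <- as.integer(probs > 0.5)
  acc_seg <- mean(pred == y)

  sids <- unique(subject_ids)
  per <- data.frame(subject_id = sids,
                    label = y[match(sids, subject_ids)],
                    n = as.integer(table(subject_ids)[sids]))
  per$vote_frac_acute <- vapply(sids, function(s)
    mean(pred[subject_ids == s]), numeric(1))
  per$mean_prob <- vapply(sids, function(s)
    mean(probs[subject_ids == s]), numeric(1))
  per$pred <- ifelse(per$vote_frac_acute > 0.5, 1L,
                     ifelse(per$vote_frac_acute < 0.5, 0L,
                            as.integer(per$mean_prob > 0.5)))
  per$correct_frac <- ifelse(per$label == 1, per$vote_frac_acute,
                             1 - per$vote_frac_acute)
  acc_sub <- mean(per$pred == per$label)

  list(acc_segment = 100 * acc_seg,
       acc_subject = 100 * acc_sub,
       segment = c(.prf(pred, y), auroc = .auroc(y, probs)),
       subject = c(.prf(per$pred, per$label),
                   auroc = .auroc(per$label, per$mean_prob)),
       per_subject = per)
}

#' Pearson product-moment correlation
#'
#' A guarded wrapper used in the ablation analyses to relate unlabeled-data
#' availability (downsampling ratios or dataset relative sizes) to the change
#' in target-task accuracy.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, nonzero variances.
#' @return The correlation coefficient.
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y)
}

.safe_paired_t <- function(d) {
  if (stats::sd(d) == 0) {
    list(estimate = mean(d), p = if (mean(d) == 0) 1 else 0,
         degenerate = TRUE)
  } else {
    tt <- stats::t.test(d)
    list(estimate = unname(tt$estimate), p = tt$p.value, degenerate = FALSE)
  }
}

#' Compare two classifiers on paired segment probabilities
#'
#' Three hypotheses on the difference in correct-class probability between
#' model A and model B over the same segments: (i) a two-tailed paired t test
#' treating segments as iid; (ii) a random-intercept linear mixed model of the
#' difference with subject as a grouping factor, testing whether the fixed
#' intercept is 0 (accounts for segments nested in subjects); (iii) a
#' two-tailed paired t test on the per-subject fraction of correctly
#' classified segments. All p values receive a Bonferroni correction with the
#' configured family size.
#'
#' @param p_a,p_b per-segment P(acute) from the two models, paired.
#' @param labels per-segment true labels.
#' @param subject_ids per-segment subject identifiers.
#' @param n_tests Bonferroni family size (default 19).
#' @return List with `t_segment`, `lme`, `t_subject` (each: estimate, raw p,
#'   Bonferroni-corrected p, degeneracy flag) and `mean_diff`.
#' @export
compareModels <- function(p_a, p_b, labels, subject_ids, n_tests = 19) {
  if (length(p_a) != length(p_b)) stop("unpaired inputs")
  y <- if (is.numeric(labels)) as.integer(labels)
    else as.integer(labels == "acute")
  corr_a <- ifelse(y == 1, p_a, 1 - p_a)
  corr_b <- ifelse(y == 1, p_b, 1 - p_b)
  d <- corr_a - corr_b
  bonf <- function(p) if (is.na(p)) NA_real_ else min(1, p * n_tests)

  ts <- .safe_paired_t(d)
  ts$p_bonf <- bonf(ts$p)

  lme_res <- if (stats::sd(d) == 0) {
    list(estimate = mean(d), p = if (mean(d) == 0) 1 else NA_real_,
         degenerate = TRUE)
  } else {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(d ~ 1 + (1 | g),
                                      data = data.frame(d = d,
                                                        g = subject_ids))),
      error = function(e) NULL)
    if (is.null(fit)) list(estimate = mean(d), p = NA_real_,
                           degenerate = TRUE)
    else {
      cf <- stats::coef(summary(fit))
      list(estimate = cf[1, "Estimate"], p = cf[1, "Pr(>|t|)"],
           degenerate = lme4::isSingular(fit))
    }
  }
  lme_res$p_bonf <- bonf(lme_res$p)

  pa_cls <- as.integer(p_a > 0.5); pb_cls <- as.integer(p_b > 0.5)
  sids <- unique(subject_ids)
  fr_a <- vapply(sids, function(s)
    mean((pa_cls == y)[subject_ids == s]), numeric(1))
  fr_b <- vapply(sids, function(s)
    mean((pb_cls == y)[subject_ids == s]), numeric(1))
  tsub <- .safe_paired_t(fr_a - fr_b)
  tsub$p_bonf <- bonf(tsub$p)

  list(mean_diff = mean(d), t_segment = ts, lme = lme_res, t_subject = tsub,
       n_tests = n_tests)
}

#' Select recordings for an ablated pretraining collection
#'
#' Downsampling keeps the stated fraction of recordings within each dataset
#' (stratified; at least one recording per retained dataset, ratio 0 keeps
#' none); leave-one-out removes exactly one dataset's recordings.
#'
#' @param dataset_ids per-recording dataset identifiers.
#' @param mode `"downsample"` or `"leave_one_out"`.
#' @param ratio downsampling fraction in `[0, 1]` (mode `"downsample"`).
#' @param dataset dataset id to remove (mode `"leave_one_out"`).
#' @param seed sampling seed.
#' @return Logical vector over recordings: `TRUE` = kept for pretraining.
#' @export
selectAblation <- function(dataset_ids, mode = c("downsample",
                                                 "leave_one_out"),
                           ratio = NULL, dataset = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "leave_one_out") {
    if (is.null(dataset) || !dataset %in% dataset_ids)
      stop(sprintf("unknown dataset id '%s'", dataset))
    return(dataset_ids != dataset)
  }
  stopifnot(!is.null(ratio), ratio >= 0, ratio <= 1)
  keep <- logical(length(dataset_ids))
  if (ratio == 0) return(keep)
  .with_seed(seed, {
    for (ds in unique(dataset_ids)) {
      idx <- which(dataset_ids == ds)
      k <- max(1L, round(ratio * length(idx)))
      keep[sample(idx, k)] <- TRUE
    }
    keep
  })
}

#' Ablation harness
#'
#' Re-runs the self-supervised pipeline on an ablated unlabeled collection
#' (always joined with the target training recordings, which are available at
#' no extra cost) and reports the change against the full-collection reference
#' run. The pipeline itself is injected as `runner(pretrain_recordings)`,
#' which must return a list with at least `acc_segment` and `acc_subject`
#' (e.g. a wrapper around pretraining, fine-tuning and
#' [evaluateClassifier()]); the same runner (and its internal seed) is used
#' for the reference, isolating the data effect.
#'
#' @param unlabeled list of unlabeled recordings (any objects; only their
#'   `dataset_ids` order matters for selection).
#' @param dataset_ids per-recording dataset ids, parallel to `unlabeled`.
#' @param runner function taking the list of pretraining recordings.
#' @param reference result of `runner` on the full collection; computed here
#'   when `NULL`.
#' @param mode,ratio,dataset,seed passed to [selectAblation()].
#' @return List: `condition`, `kept`, `result`, `reference`,
#'   `delta_acc_segment`, `delta_acc_subject`.
#' @export
ablateCollection <- function(unlabeled, dataset_ids, runner,
                             reference = NULL,
                             mode = c("downsample", "leave_one_out"),
                             ratio = NULL, dataset = NULL, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(length(unlabeled) == length(dataset_ids))
  if (is.null(reference)) reference <- runner(unlabeled)
  keep <- selectAblation(dataset_ids, mode, ratio = ratio, dataset = dataset,
                         seed = seed)
  res <- if (mode == "downsample" && identical(ratio, 1)) reference
    else runner(unlabeled[keep])
  list(condition = if (mode == "downsample")
         sprintf("downsample_%d%%", round(100 * ratio))
       else sprintf("leave_out_%s", dataset),
       kept = keep, result = res, reference = reference,
       delta_acc_segment = res$acc_segment - reference$acc_segment,
       delta_acc_subject = res$acc_subject - reference$acc_subject)
}

#' Published ablation reference tables
#'
#' Summary tables of large-scale ablation experiments with this pipeline
#' (stratified downsampling of the unlabeled collection, and leave-one-dataset
#' out), bundled as package data. Used to relate unlabeled-data availability
#' to the change in target-task accuracy via [pearsonCorr()].
#'
#' @param which `"downsampling"` or `"leave_one_out"`.
#' @return A data.frame.
#' @export
ablationReference <- function(which = c("downsampling", "leave_one_out")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("ablation_", which, ".csv"), package = "e4mood",
                   mustWork = TRUE)
  utils::read.csv(f, check.names = FALSE)
}
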