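#' @include AllClasses.R
NULL

#' Masking specification for masked prediction
#'
#' Masked runs have geometric lengths with mean `l0` (given in seconds and
#' converted per channel to samples via the sampling rate, so a 3 s run is 96
#' samples at 32 Hz but 192 at 64 Hz); unmasked runs have mean
#' `l1 = l0 * (1 - r) / r`, which makes the expected masked fraction equal the
#' masking ratio `r`. `l1` is always derived, never set independently.
#'
#' @param r masking ratio, strictly between 0 and 1 (default 0.15).
#' @param l0_s mean masked-run length in seconds (default 3).
#' @return A list of class `mask_spec` with fields `r`, `l0_s`, `l1_s`.
#' @export
maskSpec <- function(r = 0.15, l0_s = 3) {
  stopifnot(r > 0, r < 1, l0_s > 0)
  structure(list(r = r, l0_s = l0_s, l1_s = l0_s * (1 - r) / r),
            class = "mask_spec")
}

#' Sample a Boolean channel mask
#'
#' Alternating masked/unmasked runs whose lengths are geometric on
#' `{1, 2, ...}` with means `l0_s * fs` and `l1_s * fs` samples; the first run
#' is masked with probability `r`; the final run is truncated at the sequence
#' end. Masks are sampled independently per channel by the caller.
#'
#' @param n_samples mask length in samples (>= 1).
#' @param spec a [maskSpec()].
#' @param fs sampling rate of the channel, Hz.
#' @return Logical vector: `TRUE` = masked (zeroed).
#' @export
sampleMask <- function(n_samples, spec = maskSpec(), fs = 32) {
  stopifnot(inherits(spec, "mask_spec"), n_samples >= 1)
  l0 <- max(1, spec$l0_s * fs)
  l1 <- max(1, spec$l1_s * fs)
  # geometric on {1,2,...} with mean m: 1 + rgeom(p = 1/m)
  rgeo <- function(k, m) 1L + stats::rgeom(k, prob = 1 / m)
  masked <- stats::runif(1) < spec$r
  out <- logical(n_samples)
  pos <- 0L
  # draw runs in blocks to limit R-level looping
  while (pos < n_samples) {
    k <- max(8L, ceiling((n_samples - pos) / (l0 + l1) * 2.5))
    runs <- as.vector(rbind(rgeo(k, if (masked) l0 else l1),
                            rgeo(k, if (masked) l1 else l0)))
    states <- rep(c(masked, !masked), k)
    for (i in seq_along(runs)) {
      take <- min(runs[i], n_samples - pos)
      if (take > 0L && states[i]) out[(pos + 1L):(pos + take)] <- TRUE
      pos <- pos + take
      if (pos >= n_samples) break
    }
  }
  out
}

#' Sample per-channel masks for a segment
#'
#' @param segments a standardized [SegmentSet-class].
#' @param i segment index.
#' @param spec a [maskSpec()].
#' @return Named list of logical masks, one per channel.
#' @export
sampleSegmentMasks <- function(segments, i, spec = maskSpec()) {
  fs <- segments@fs
  lapply(stats::setNames(names(fs), names(fs)), function(ch)
    sampleMask(round(segments@omega * fs[[ch]]), spec, fs[[ch]]))
}

#' Zero out masked positions
#'
#' Multiplies each channel by its Boolean mask complement: masked positions
#' become 0, all others are untouched.
#'
#' @param seg named list of channel arrays.
#' @param masks named list of logical masks (`TRUE` = masked), same lengths.
#' @return Corrupted copy of `seg`.
#' @export
applyMask <- function(seg, masks) {
  for (ch in names(masks)) {
    if (length(masks[[ch]]) != length(seg[[ch]]))
      stop(sprintf("mask length mismatch on channel %s", ch))
    seg[[ch]][masks[[ch]]] <- 0
  }
  seg
}

#' Masked-prediction loss (masked RMSE)
#'
#' `sqrt( (1/|M|) * sum_{(t,c) in M} (x - xhat)^2 )` where `M` is the union of
#' masked positions across channels; unmasked positions never contribute.
#'
#' @param original,reconstruction named lists of channel arrays.
#' @param masks named list of logical masks.
#' @return Scalar loss; errors when no position is masked.
#' @export
mpLoss <- function(original, reconstruction, masks) {
  sq <- 0; m <- 0L
  for (ch in names(masks)) {
    k <- masks[[ch]]
    sq <- sq + sum((original[[ch]][k] - reconstruction[[ch]][k])^2)
    m <- m + sum(k)
  }
  if (m == 0L) stop("masked RMSE undefined: empty mask")
  sqrt(sq / m)
}

#' The six channel transformations
#'
#' @return Character vector of transformation kinds, in label order.
#' @export
transformKinds <- function() {
  c("identity", "gaussian_noise", "magnitude_warp", "permutation",
    "time_warp", "crop")
}

#' Sample a per-channel transformation assignment
#'
#' One of the six kinds iid uniform per channel.
#'
#' @param n_channels number of channels.
#' @return Integer vector of kind indices (1..6) with kind names.
#' @export
sampleTransforms <- function(n_channels) {
  k <- sample.int(6L, n_channels, replace = TRUE)
  stats::setNames(k, NULL)
}

# smooth random curve through `knots` interior knots (plus endpoints),
# values ~ N(1, sd), evaluated at n points via cubic spline
.warp_curve <- function(n, knots = 4, sd = 0.2) {
  xk <- seq(1, n, length.out = knots + 2)
  yk <- stats::rnorm(knots + 2, mean = 1, sd = sd)
  stats::spline(xk, yk, xout = seq_len(n))$y
}

#' Apply one transformation to a channel
#'
#' All transformations preserve the array length; `identity` is bit-exact.
#' Applied to standardized signals, so `noise_sd` is in SD units. Defaults:
#' Gaussian noise sd 0.1; magnitude warp = multiplication by a cubic-spline
#' envelope with 4 interior knots of SD 0.2 around 1; permutation = 4 equal
#' blocks shuffled; time warp = cubic-spline time remap (4 knots, SD 0.2) with
#' linear resampling back to length; crop = a contiguous 50% window stretched
#' back to full length by linear interpolation.
#'
#' @param x numeric channel array.
#' @param kind index into [transformKinds()] or a kind name.
#' @param noise_sd,warp_knots,warp_sd,n_blocks,crop_frac parameters.
#' @return Transformed array, same length as `x`.
#' @export
applyTransform <- function(x, kind, noise_sd = 0.1, warp_knots = 4,
                           warp_sd = 0.2, n_blocks = 4, crop_frac = 0.5) {
  if (is.character(kind)) kind <- match(kind, transformKinds())
  if (is.na(kind) || kind < 1 || kind > 6) stop("unknown transformation kind")
  n <- length(x)
  switch(kind,
    x,                                                     # identity
    x + stats::rnorm(n, 0, noise_sd),                      # gaussian_noise
    x * .warp_curve(n, warp_knots, warp_sd),               # magnitude_warp
    {                                                      # permutation
      bl <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
      idx <- unlist(bl[sample.int(n_blocks)], use.names = FALSE)
      x[idx]
    },
    {                                                      # time_warp
      speed <- pmax(.warp_curve(n, warp_knots, warp_sd), 0.05)
      tw <- cumsum(speed)
      tw <- 1 + (tw - tw[1]) / (tw[n] - tw[1]) * (n - 1)
      stats::approx(seq_len(n), x, xout = tw, rule = 2)$y
    },
    {                                                      # crop
      w <- max(2L, floor(n * crop_frac))
      s0 <- sample.int(n - w + 1L, 1L)
      piece <- x[s0:(s0 + w - 1L)]
      stats::approx(seq_len(w), piece, xout = seq(1, w, length.out = n))$y
    })
}

#' Transformation-prediction loss (channel-average cross-entropy)
#'
#' `(1/C) * sum_c -log p_{c, j_c}` with `p` the softmax of the per-channel
#' logits and `j_c` the transformation actually applied to channel `c`.
#'
#' @param logits matrix, channels x 6.
#' @param assignment integer vector of true kinds (1..6), length = channels.
#' @return Scalar loss.
#' @export
tpLoss <- function(logits, assignment) {
  if (!is.matrix(logits) || ncol(logits) != 6L ||
      nrow(logits) != length(assignment))
    stop("logits must be channels x 6, matching the assignment")
  z <- logits - apply(logits, 1L, max)
  logp <- z - log(rowSums(exp(z)))
  -mean(logp[cbind(seq_len(nrow(logits)), assignment)])
}
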