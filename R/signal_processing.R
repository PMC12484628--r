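#' Window-based transition detection and ISI mitigation
#'
#' A transition between samples t and t+1 is declared when the means of the
#' w-sample windows just before (inclusive) and just after (exclusive) t
#' differ by more than a threshold. Sweeping the threshold yields ROC curves
#' for segmentation. Intersymbol interference (ISI) from the band-limiting
#' filter is mitigated by removing samples that sit mid-ramp between two
#' levels: any interior sample differing from both neighbours by at least
#' 2*floor(sigma_hat) pA.
#'
#' @name signal_processing
NULL

#' Detect k-mer transitions with a sliding window
#'
#' For each gap t (between samples t and t+1, 1-based) with a full w-sample
#' window on both sides, computes a = mean of the w samples up to t and b = mean of the w samples after t
#' and flags a transition when |a-b| > thresh. Gaps too close to the ends are
#' scored 0 and never flagged.
#'
#' @param trace a `signal_trace` (or numeric vector).
#' @param w window length in samples (default 3: dwells are rarely shorter).
#' @param thresh threshold in pA.
#' @return list with `flags` (logical, length M-1) and `score` (|a-b|, pA).
#' @export
detect_transitions <- function(trace, w = 3, thresh = 0) {
  z <- if (inherits(trace, "signal_trace")) trace$samples else as.numeric(trace)
  M <- length(z)
  if (M < 2 * w) stop("signal too short: need at least 2w = ", 2 * w, " samples")
  cs <- cumsum(z)
  score <- numeric(M - 1)
  gaps <- w:(M - w)
  a <- (cs[gaps] - c(0, cs)[gaps - w + 1]) / w
  b <- (cs[gaps + w] - cs[gaps]) / w
  score[gaps] <- abs(a - b)
  list(flags = score > thresh, score = score)
}

#' ROC curve for segmentation
#'
#' Pools all gaps of all traces. A gap is a positive when a true transition
#' lies within +/- `tol` samples of it (the low-pass filter can shift the
#' apparent transition by about one sample). TPR/FPR are computed for each
#' threshold in `thresholds` with the detector rule score > thresh; AUC is the
#' trapezoid over the swept points plus the (0,0) and (1,1) endpoints.
#'
#' @param traces list of `signal_trace` objects carrying `truth_transitions`.
#' @param w detector window.
#' @param thresholds numeric vector; defaults to the sorted unique scores.
#' @param tol positive-gap tolerance in samples.
#' @return list with `table` (data.frame: thresh, FPR, TPR) and `auc`.
#' @export
roc_curve <- function(traces, w = 3, thresholds = NULL, tol = 1) {
  if (inherits(traces, "signal_trace")) traces <- list(traces)
  scores <- numeric(0)
  is_pos <- logical(0)
  for (tr in traces) {
    if (is.null(tr$truth_transitions)) stop("trace lacks ground-truth transitions")
    det <- detect_transitions(tr, w = w, thresh = 0)
    M1 <- length(det$score)
    pos <- rep(FALSE, M1)
    for (t0 in tr$truth_transitions) {
      lo <- max(1, t0 - tol); hi <- min(M1, t0 + tol)
      pos[lo:hi] <- TRUE
    }
    scores <- c(scores, det$score)
    is_pos <- c(is_pos, pos)
  }
  nP <- sum(is_pos); nN <- sum(!is_pos)
  if (nP == 0 || nN == 0) stop("AUC undefined: need both positive and negative gaps")
  if (is.null(thresholds)) {
    thresholds <- sort(unique(scores))
    if (length(thresholds) > 1024) {   # decimate the sweep for large batches
      thresholds <- unique(stats::quantile(scores, seq(0, 1, length.out = 1024),
                                           names = FALSE, type = 1))
    }
  }
  sp <- sort(scores[is_pos]); sn <- sort(scores[!is_pos])
  tpr <- (nP - findInterval(thresholds, sp)) / nP   # count of scores > th
  fpr <- (nN - findInterval(thresholds, sn)) / nN
  tab <- data.frame(thresh = thresholds, FPR = fpr, TPR = tpr)
  o <- order(-thresholds)   # sweep thresholds downward: (FPR, TPR) non-decreasing
  xs <- c(0, fpr[o], 1)
  ys <- c(0, tpr[o], 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  list(table = tab[order(tab$thresh), ], auc = auc)
}

#' Remove ISI-corrupted samples
#'
#' Single pass over the original signal: every interior sample z_t with
#' |z_t - z_(t-1)| >= 2*floor(sigma_hat) and |z_t - z_(t+1)| >= 2*floor(sigma_hat)
#' is removed (endpoints kept). Such samples sit on the sharp ramps the
#' low-pass filter introduces at k-mer transitions and carry mixed-level
#' values.
#'
#' @param trace a `signal_trace` (or numeric vector).
#' @param sigma_hat mean per-k-mer level standard deviation (pA); must give
#'   2*floor(sigma_hat) >= 2, i.e. sigma_hat >= 1.
#' @return list with `trace` (compacted `signal_trace`), `removed` (indices).
#' @export
mitigate_isi <- function(trace, sigma_hat) {
  z <- if (inherits(trace, "signal_trace")) trace$samples else as.numeric(trace)
  fs <- if (inherits(trace, "signal_trace")) trace$fs else 4000
  thr <- 2 * floor(sigma_hat)
  if (thr <= 0) stop("2*floor(sigma_hat) must be positive; pass sigma_hat >= 1")
  M <- length(z)
  if (M < 3) stop("signal too short for ISI mitigation (need >= 3 samples)")
  t_ <- 2:(M - 1)
  drop <- t_[abs(z[t_] - z[t_ - 1]) >= thr & abs(z[t_] - z[t_ + 1]) >= thr]
  kept <- if (length(drop) > 0) z[-drop] else z
  out <- new_signal_trace(kept, fs = fs)
  out$source_id <- if (inherits(trace, "signal_trace")) trace$source_id else NULL
  list(trace = out, removed = drop)
}

#' Export an ROC table to TSV
#'
#' @param roc result of [roc_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(roc$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
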