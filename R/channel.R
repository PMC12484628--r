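#' Simplified nanopore channel simulator
#'
#' The simulator follows the standard squiggle-generation recipe: one nominal
#' current level per k-mer window (table lookup), repetition of each level for
#' a geometric random dwell (mean `d` samples), a causal first-order low-pass
#' filter with a 950 Hz cut-off to band-limit the square wave, and additive
#' i.i.d. Gaussian noise. Ground-truth dwells and transition positions are
#' recorded on the trace for segmentation benchmarking.
#'
#' @name channel_simulator
NULL

new_signal_trace <- function(samples, fs = 4000, truth_dwells = NULL, source_id = NULL) {
  truth_transitions <- NULL
  if (!is.null(truth_dwells)) {
    stopifnot(all(truth_dwells >= 1), length(samples) == sum(truth_dwells))
    cs <- cumsum(truth_dwells)
    truth_transitions <- cs[-length(cs)]   # gap index: between sample t and t+1
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 truth_dwells = truth_dwells,
                 truth_transitions = truth_transitions,
                 source_id = source_id),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("signal_trace: %d samples @ %g Hz%s\n", length(x$samples), x$fs,
              if (!is.null(x$truth_dwells)) sprintf(", %d k-mer dwells", length(x$truth_dwells)) else ""))
  invisible(x)
}

#' Ideal per-k-mer current levels for a sequence
#'
#' One value per length-k window: the model mean of that k-mer
#' (context-independent lookup).
#'
#' @param seq DNA string with nchar(seq) >= k.
#' @param model a [kmer_model].
#' @return numeric vector of length `nchar(seq) - k + 1` (pA).
#' @export
ideal_levels <- function(seq, model) {
  k <- model$k
  m <- nchar(seq)
  stopifnot(m >= k)
  wins <- substring(seq, 1:(m - k + 1), k:m)
  mu <- model$mean_pA[wins]
  if (anyNA(mu)) stop("window not present in model: ", wins[which(is.na(mu))[1]])
  unname(mu)
}

#' Sample geometric dwell times
#'
#' With `min_dwell = 1` (the default) dwells are i.i.d. geometric on
#' {1, 2, ...} with success probability 1/d, hence mean d samples per k-mer.
#' A larger floor gives the shifted geometric on {min_dwell, ...} with the
#' same mean d (dwell = min_dwell - 1 + geometric with mean
#' d - min_dwell + 1); the channel simulator uses floor 3, since observed
#' nanopore dwell times are rarely below 3 samples. With fs = 4000 Hz and a
#' translocation speed of ~450 bases/s the physical mean dwell is
#' fs/450 = 8.89 samples; the decoder's working value is d = 8.
#'
#' @param n number of dwells.
#' @param d expected dwell in samples (> min_dwell).
#' @param seed optional integer seed.
#' @param min_dwell smallest possible dwell.
#' @return integer vector of length n, all >= min_dwell.
#' @export
sample_dwells <- function(n, d = 8, seed = NULL, min_dwell = 1) {
  if (d <= min_dwell) stop("expected dwell d must be > min_dwell")
  run <- function() {
    (min_dwell - 1L) + stats::rgeom(n, prob = 1 / (d - min_dwell + 1)) + 1L
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# Causal first-order low-pass via the bilinear transform:
# y[n] = b (x[n] + x[n-1]) - a1 y[n-1], unity DC gain.
lowpass_filter <- function(x, cutoff, fs, init = x[1]) {
  if (!is.finite(cutoff)) return(x)
  K <- tan(pi * cutoff / fs)
  b <- K / (K + 1)
  a1 <- (K - 1) / (K + 1)
  y <- numeric(length(x))
  prev_x <- init
  prev_y <- init
  for (i in seq_along(x)) {
    y[i] <- b * (x[i] + prev_x) - a1 * prev_y
    prev_x <- x[i]
    prev_y <- y[i]
  }
  y
}

#' Synthesize a current signal for a DNA sequence
#'
#' Pipeline: per-window ideal level -> per-k-mer dwell repetition (geometric,
#' mean `d`) -> causal first-order low-pass at `cutoff` Hz (bilinear
#' transform, state initialized to the first level; `Inf` disables) ->
#' additive N(0, noise_sigma^2) noise (`0` disables).
#'
#' @param seq DNA string.
#' @param model a [kmer_model].
#' @param d expected dwell in samples.
#' @param noise_sigma noise standard deviation in pA.
#' @param cutoff low-pass cut-off in Hz (`Inf` = no filter).
#' @param fs sampling rate in Hz.
#' @param seed optional integer seed.
#' @param dwells optional fixed dwell vector (overrides sampling).
#' @param min_dwell dwell floor passed to [sample_dwells()]; the default 3
#'   reflects that nanopore dwell times are rarely shorter.
#' @return a `signal_trace` with ground truth attached.
#' @export
synthesize_signal <- function(seq, model, d = 8, noise_sigma = 1.0,
                              cutoff = 950, fs = 4000, seed = NULL,
                              dwells = NULL, min_dwell = 3) {
  stopifnot(noise_sigma >= 0)
  levels <- ideal_levels(seq, model)
  run <- function() {
    dw <- if (is.null(dwells)) sample_dwells(length(levels), d, min_dwell = min_dwell) else dwells
    stopifnot(length(dw) == length(levels), all(dw >= 1))
    square <- rep(levels, dw)
    z <- lowpass_filter(square, cutoff, fs)
    if (noise_sigma > 0) z <- z + stats::rnorm(length(z), 0, noise_sigma)
    new_signal_trace(z, fs = fs, truth_dwells = dw)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

#' Simulate S independent reads of one molecule
#'
#' Each read uses a seed derived from (`seed`, read index), so the set is
#' reproducible yet the reads are mutually independent.
#'
#' @param seq DNA string.
#' @param model a [kmer_model].
#' @param S number of reads (>= 1).
#' @param seed master integer seed.
#' @param random_dwell draw geometric dwells (default); `FALSE` fixes every
#'   dwell at `d` samples (the fully deterministic channel used together with
#'   zero noise and no filter).
#' @param d expected dwell in samples.
#' @param ... passed to [synthesize_signal()].
#' @return list of `signal_trace`.
#' @export
simulate_reads <- function(seq, model, S = 1, seed = 1, random_dwell = TRUE,
                           d = 8, ...) {
  stopifnot(S >= 1)
  dwells <- if (random_dwell) NULL else rep(ceiling(d), nchar(seq) - model$k + 1)
  lapply(seq_len(S), function(i) {
    tr <- synthesize_signal(seq, model, d = d, seed = derive_seed(seed, i),
                            dwells = dwells, ...)
    tr$source_id <- sprintf("read_%d", i)
    tr
  })
}

#' Write / read signal traces as plain text
#'
#' One sample per line; "#"-prefixed header lines carry source_id, fs, and
#' the dwell ground truth (comma-separated) when present.
#'
#' @param trace a `signal_trace`.
#' @param path file path.
#' @return `path` invisibly (write) / a `signal_trace` (read).
#' @export
write_signal <- function(trace, path) {
  hdr <- c(sprintf("# source_id=%s", trace$source_id %||% "NA"),
           sprintf("# fs=%g", trace$fs))
  if (!is.null(trace$truth_dwells)) {
    hdr <- c(hdr, sprintf("# dwells=%s", paste(trace$truth_dwells, collapse = ",")))
  }
  writeLines(c(hdr, format(trace$samples, digits = 17, trim = TRUE, scientific = FALSE)), path)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    sub(sprintf("^# %s=", key), "", m[1])
  }
  fs <- as.numeric(get("fs") %||% "4000")
  dw <- get("dwells")
  dwells <- if (!is.null(dw)) as.integer(strsplit(dw, ",")[[1]]) else NULL
  sid <- get("source_id")
  if (!is.null(sid) && sid == "NA") sid <- NULL
  new_signal_trace(as.numeric(body), fs = fs, truth_dwells = dwells, source_id = sid)
}
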