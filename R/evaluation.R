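#' Error profiling and batch sweeps
#'
#' Coding performance is measured by the Levenshtein (edit) distance between
#' the stored and basecalled sequences, decomposed into insertions, deletions
#' and substitutions along one optimal alignment (tie preference:
#' substitution > deletion > insertion, so the decomposition is
#' deterministic), plus bit-error rates after decoding and the analytic
#' redundancy bound for edit-correcting block codes.
#'
#' @name evaluation
NULL

#' Levenshtein distance
#'
#' @param a,b character strings.
#' @return integer edit distance.
#' @export
levenshtein_distance <- function(a, b) lev_distance_cpp(a, b)

#' Levenshtein profile with error-type breakdown
#'
#' @param a,b character strings (ops transform `a` into `b`).
#' @return an `error_profile` list: `edit_distance`, `insertions`,
#'   `deletions`, `substitutions`; the three counts always sum to the
#'   distance.
#' @export
levenshtein_profile <- function(a, b) {
  v <- lev_profile_cpp(a, b)
  structure(list(edit_distance = v[1], insertions = v[2],
                 deletions = v[3], substitutions = v[4]),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("edit distance %d (ins %d, del %d, sub %d)\n",
              x$edit_distance, x$insertions, x$deletions, x$substitutions))
  invisible(x)
}

#' Bit-error rate
#'
#' Hamming fraction over the length of `x`; a shorter/longer `x_hat` is
#' zero-filled/truncated to that length first (mismatches counted), matching
#' the fixed-length decode contract.
#'
#' @param x,x_hat integer vectors of 0/1.
#' @return fraction in `[0, 1]`.
#' @export
bit_error_rate <- function(x, x_hat) {
  x <- as.integer(x)
  n <- length(x)
  h <- integer(n)
  m <- min(n, length(x_hat))
  if (m > 0) h[seq_len(m)] <- as.integer(x_hat)[seq_len(m)]
  mean(x != h)
}

#' Redundancy bound for edit-correcting codes
#'
#' The best block codes correcting t edit errors (insertions, deletions,
#' substitutions) in a q-ary sequence of length n need at least
#' 2t(2 log2 n + log2 q) redundant bits.
#'
#' @param n sequence length.
#' @param q alphabet size.
#' @param t number of correctable edit errors.
#' @return list with `bits` and `symbols` (bits / log2(q)).
#' @export
edit_correcting_redundancy <- function(n, q, t) {
  stopifnot(n >= 2, q >= 2, t >= 1)
  bits <- 2 * t * (2 * log2(n) + log2(q))
  list(bits = bits, symbols = bits / log2(q))
}

#' Delta sweep: encode, simulate, basecall, profile
#'
#' For each delta: draws sequences (uniform random sequences at delta = 0,
#' matching the unconstrained baseline; state-split encodings of random
#' payload bits at delta > 0), pads them, simulates one read each through the
#' channel, basecalls with the delta-matched graph, removes padding and
#' profiles the errors against the unpadded truth.
#'
#' @param model a [kmer_model].
#' @param deltas numeric vector of thresholds (pA).
#' @param n_seqs sequences per delta.
#' @param seq_len unpadded sequence length in bases.
#' @param seed master seed.
#' @param max_run homopolymer cap for the constrained graphs.
#' @param q_max encoder power bound passed to [choose_pq()].
#' @param d,noise_sigma,cutoff,fs channel parameters.
#' @param isi apply ISI mitigation before Viterbi.
#' @param random_dwell geometric dwells (default) or fixed dwells of d
#'   samples (the deterministic channel).
#' @return data.frame with one row per delta: mean/percentile edit distance
#'   and mean insertion/deletion/substitution counts.
#' @export
run_delta_sweep <- function(model, deltas = c(0, 4, 8), n_seqs = 100,
                            seq_len = 186, seed = 1, max_run = 3, q_max = 6,
                            d = 8, noise_sigma = 1.0, cutoff = 950, fs = 4000,
                            isi = TRUE, random_dwell = TRUE) {
  rows <- lapply(deltas, function(delta) {
    if (delta == 0) {
      graph <- build_constrained_graph(model, delta = 0, max_run = Inf)
      fsm <- NULL
    } else {
      graph <- build_constrained_graph(model, delta = delta, max_run = max_run)
      fsm <- design_codec(graph, q_max = q_max)
    }
    hmm <- build_hmm(graph, model, d = d)
    profs <- vector("list", n_seqs)
    for (i in seq_len(n_seqs)) {
      s_i <- derive_seed(seed + round(1000 * delta), i)
      if (is.null(fsm)) {
        truth <- random_walk_sequence(graph, seq_len, seed = s_i)
      } else {
        n_words <- (seq_len - fsm$k) %/% fsm$q - fsm$flush_words
        bits <- withr::with_seed(s_i, sample(0:1, n_words * fsm$p, replace = TRUE))
        truth <- encode_bits(fsm, bits)$seq
      }
      pad <- attach_padding(truth, graph, seed = s_i)
      dwells <- if (random_dwell) NULL else
        rep(ceiling(d), nchar(pad$padded) - model$k + 1)
      trace <- synthesize_signal(pad$padded, model, d = d, noise_sigma = noise_sigma,
                                 cutoff = cutoff, fs = fs, seed = s_i,
                                 dwells = dwells)
      call <- basecall(trace, graph, model, d = d, isi = isi, hmm = hmm)
      trimmed <- remove_padding(call, pad$front_pad, nchar(truth))$read
      profs[[i]] <- levenshtein_profile(trimmed, truth)
    }
    ed <- vapply(profs, `[[`, numeric(1), "edit_distance")
    data.frame(delta = delta,
               mean_edit = mean(ed),
               p10 = unname(stats::quantile(ed, 0.1)),
               p90 = unname(stats::quantile(ed, 0.9)),
               ins = mean(vapply(profs, `[[`, numeric(1), "insertions")),
               del = mean(vapply(profs, `[[`, numeric(1), "deletions")),
               sub = mean(vapply(profs, `[[`, numeric(1), "substitutions")))
  })
  do.call(rbind, rows)
}
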