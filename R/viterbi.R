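#' HMM construction and Viterbi basecalling
#'
#' Hidden states are the k-mers of the (unsplit) constrained de Bruijn graph.
#' At each sample the molecule stays put with probability 1 - 1/d (geometric
#' dwell, mean d samples) or advances along one of the graph edges, all
#' advances equally likely: P(i -> j) = (1/d) / outdeg(i). Emissions are
#' Gaussian with the model's per-k-mer mean and standard deviation. The
#' Viterbi decode is exact (full dynamic program, no beam), with ties broken
#' toward the lexicographically smaller k-mer.
#'
#' @name viterbi_basecaller
NULL

#' Build the k-mer HMM
#'
#' @param graph an irreducible `debruijn_graph`.
#' @param model the [kmer_model] supplying emission parameters.
#' @param d expected dwell time in samples (> 1).
#' @return an `hmm_spec`: states, log self/transition probabilities, emission
#'   parameters, uniform initial distribution.
#' @export
build_hmm <- function(graph, model, d = 8) {
  stopifnot(d > 1)
  n <- length(graph$nodes)
  outdeg <- tabulate(graph$from, nbins = n)
  if (any(outdeg == 0)) stop("graph has a state with out-degree 0 (not irreducible)")
  elogp <- log((1 / d) / outdeg[graph$from])
  mu <- unname(model$mean_pA[graph$nodes])
  sigma <- unname(model$stdev_pA[graph$nodes])
  if (anyNA(mu)) stop("graph nodes missing from model")
  structure(list(states = graph$nodes, k = graph$k, d = d,
                 efrom = graph$from, eto = graph$to, elogp = elogp,
                 log_self = log(1 - 1 / d), mu = mu, sigma = sigma),
            class = "hmm_spec")
}

#' Row-stochastic transition matrix of an HMM (dense; diagnostics/tests)
#'
#' @param hmm an `hmm_spec`.
#' @return dense matrix of transition probabilities.
#' @export
hmm_transition_matrix <- function(hmm) {
  n <- length(hmm$states)
  P <- matrix(0, n, n)
  P[cbind(hmm$efrom, hmm$eto)] <- P[cbind(hmm$efrom, hmm$eto)] + exp(hmm$elogp)
  diag(P) <- diag(P) + exp(hmm$log_self)
  P
}

#' Exact Viterbi state path
#'
#' @param hmm an `hmm_spec`.
#' @param trace a `signal_trace` or numeric vector.
#' @return integer vector of state indices (length M).
#' @export
viterbi_path <- function(hmm, trace) {
  z <- if (inherits(trace, "signal_trace")) trace$samples else as.numeric(trace)
  stopifnot(length(z) >= 1)
  viterbi_core(z, hmm$mu, hmm$sigma, hmm$efrom, hmm$eto, hmm$elogp, hmm$log_self)
}

#' Collapse a state path to a base sequence
#'
#' Self-loops are dwell; every state change appends the last base of the new
#' k-mer. Output length = k + number of non-self steps.
#'
#' @param path integer state indices.
#' @param states k-mer strings indexed by the path.
#' @return DNA string.
#' @export
path_to_sequence <- function(path, states) {
  k <- nchar(states[1])
  changes <- path[c(TRUE, diff(path) != 0)]
  paste0(states[changes[1]],
         paste(substr(states[changes[-1]], k, k), collapse = ""))
}

#' Basecall a signal
#'
#' Composition of ISI mitigation (optional, threshold from the model's
#' sigma_hat), exact Viterbi decoding over the delta-matched graph, and path
#' collapse.
#'
#' @param trace a `signal_trace`.
#' @param graph the `debruijn_graph` to decode over (same delta as encoder;
#'   a delta = 0 graph gives the unconstrained baseline).
#' @param model the [kmer_model].
#' @param d expected dwell in samples.
#' @param isi apply ISI mitigation first?
#' @param hmm optionally a prebuilt `hmm_spec` (skips [build_hmm()]).
#' @return basecalled DNA string.
#' @export
basecall <- function(trace, graph, model, d = 8, isi = TRUE, hmm = NULL) {
  if (is.null(hmm)) hmm <- build_hmm(graph, model, d = d)
  if (isi) trace <- mitigate_isi(trace, model$sigma_hat)$trace
  path <- viterbi_path(hmm, trace)
  path_to_sequence(path, hmm$states)
}
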