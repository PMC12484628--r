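# independent implementations used as oracles (kept deliberately naive)

# plain Levenshtein DP without backtrace
lev_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, integer(m))
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j] + (A[i] != B[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  as.integer(prev[m + 1])
}

# exhaustive directed-path count with `len` edges, by DFS
count_paths_oracle <- function(graph, len) {
  n <- length(graph$nodes)
  adj <- split(graph$to, factor(graph$from, levels = seq_len(n)))
  total <- 0
  recurse <- function(v, remaining) {
    if (remaining == 0) { total <<- total + 1; return(invisible()) }
    for (w in adj[[v]]) recurse(w, remaining - 1)
  }
  for (v in seq_len(n)) recurse(v, len)
  total
}

# exhaustive Viterbi: argmax over all state sequences of length T
viterbi_oracle <- function(hmm, z) {
  n <- length(hmm$states)
  Tn <- length(z)
  P <- hmm_transition_matrix(hmm)
  logP <- log(P)
  em <- function(j, zt) stats::dnorm(zt, hmm$mu[j], hmm$sigma[j], log = TRUE)
  best <- -Inf; best_path <- NULL
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), Tn)))
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    s <- -log(n) + em(p[1], z[1])
    okpath <- TRUE
    if (Tn > 1) for (t in 2:Tn) {
      if (!is.finite(logP[p[t - 1], p[t]])) { okpath <- FALSE; break }
      s <- s + logP[p[t - 1], p[t]] + em(p[t], z[t])
    }
    if (okpath && s > best + 1e-12) { best <- s; best_path <- p }
  }
  list(score = best, path = unname(best_path))
}

# score of a given state path under an hmm (for comparing DP vs oracle)
viterbi_path_score <- function(hmm, z, path) {
  P <- log(hmm_transition_matrix(hmm))
  s <- -log(length(hmm$states)) +
    stats::dnorm(z[1], hmm$mu[path[1]], hmm$sigma[path[1]], log = TRUE)
  if (length(z) > 1) for (t in 2:length(z)) {
    s <- s + P[path[t - 1], path[t]] +
      stats::dnorm(z[t], hmm$mu[path[t]], hmm$sigma[path[t]], log = TRUE)
  }
  s
}

# write a hand-specified k-mer model table and load it
model_from_means <- function(means, stdevs = NULL) {
  k <- nchar(names(means)[1])
  kmers <- all_kmers(k)
  mu <- means[kmers]
  if (is.null(stdevs)) stdevs <- stats::setNames(rep(2, length(kmers)), kmers)
  path <- tempfile(fileext = ".tsv")
  writeLines(c("kmer\tlevel_mean\tlevel_stdv",
               sprintf("%s\t%.6f\t%.6f", kmers, mu, stdevs[kmers])), path)
  load_kmer_model(path)
}

# bare trace with ground-truth dwells (for detector/ROC edge cases)
new_signal_trace_for_test <- function(samples, dwells) {
  porecode:::new_signal_trace(samples, truth_dwells = dwells)
}
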