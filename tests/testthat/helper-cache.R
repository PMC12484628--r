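# shared fixtures, built lazily and cached for the whole run
.pc <- new.env(parent = emptyenv())

pc_model <- function(k, seed = 1) {
  key <- sprintf("model_%d_%d", k, seed)
  if (is.null(.pc[[key]])) .pc[[key]] <- synthetic_kmer_model(k = k, seed = seed)
  .pc[[key]]
}

pc_graph <- function(k, delta, max_run = 3, seed = 1) {
  key <- sprintf("graph_%d_%g_%s_%d", k, delta, format(max_run), seed)
  if (is.null(.pc[[key]])) {
    .pc[[key]] <- build_constrained_graph(pc_model(k, seed), delta = delta,
                                          max_run = max_run)
  }
  .pc[[key]]
}

pc_codec <- function(k, delta, max_run = 3, seed = 1, q_max = 6) {
  key <- sprintf("codec_%d_%g_%s_%d_%d", k, delta, format(max_run), seed, q_max)
  if (is.null(.pc[[key]])) {
    .pc[[key]] <- design_codec(pc_graph(k, delta, max_run, seed), q_max = q_max)
  }
  .pc[[key]]
}
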