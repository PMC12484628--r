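test_that("HMM rows are stochastic with the stated dwell split", {
  g <- pc_graph(3, 4, 3)
  m <- pc_model(3)
  hmm <- build_hmm(g, m, d = 8)
  # row mass: self 1 - 1/d plus (1/d)/outdeg per out-edge
  mass <- tapply(exp(hmm$elogp), hmm$efrom, sum)
  rows <- exp(hmm$log_self) + as.numeric(mass)
  expect_true(all(abs(rows - 1) < 1e-12))
  # a state with 4 out-edges at d = 8: self 7/8, each neighbour 1/32
  outdeg <- tabulate(hmm$efrom, nbins = length(hmm$states))
  s4 <- which(outdeg == 4)[1]
  expect_equal(exp(hmm$log_self), 7 / 8)
  expect_equal(unname(exp(hmm$elogp[hmm$efrom == s4])), rep(1 / 32, 4))
  # d = 2: self probability 1/2
  expect_equal(exp(build_hmm(g, m, d = 2)$log_self), 1 / 2)
})

test_that("full k=6 HMM rows sum to one within 1e-12", {
  hmm <- build_hmm(pc_graph(6, 0, Inf), pc_model(6), d = 8)
  mass <- numeric(length(hmm$states))
  agg <- tapply(exp(hmm$elogp), hmm$efrom, sum)
  mass[as.integer(names(agg))] <- agg
  expect_true(all(abs(mass + exp(hmm$log_self) - 1) < 1e-12))
})

test_that("a single sample at a state's mean decodes to that state", {
  means <- stats::setNames(seq(50, 113, length.out = 64), all_kmers(3))
  stdev <- stats::setNames(rep(2, 64), all_kmers(3))
  m <- model_from_means(means, stdev)
  g <- build_constrained_graph(m, delta = 0, max_run = Inf)
  hmm <- build_hmm(g, m)
  s <- 17L
  path <- viterbi_path(hmm, unname(m$mean_pA[g$nodes[s]]))
  expect_identical(as.integer(path), s)
})

test_that("Viterbi equals exhaustive search on toy HMMs", {
  # 3-state toy over a k=1 alphabet subset; traces up to length 6
  toy_graph <- structure(list(k = 1, delta = 0, max_run = Inf,
                              nodes = c("A", "C", "G"),
                              from = c(1, 1, 2, 3, 3),
                              to = c(2, 3, 1, 1, 2),
                              weight = rep(1, 5), mean_pA = NULL),
                         class = "debruijn_graph")
  means <- stats::setNames(c(90, 100, 110, 120), all_kmers(1))
  m <- model_from_means(means, stats::setNames(c(2, 3, 2.5, 2), all_kmers(1)))
  hmm <- build_hmm(toy_graph, m, d = 4)
  set.seed(19)
  for (trial in 1:12) {
    Tn <- sample(2:6, 1)
    z <- rnorm(Tn, sample(c(90, 100, 110), Tn, replace = TRUE), 4)
    dp <- viterbi_path(hmm, z)
    oracle <- viterbi_oracle(hmm, z)
    expect_equal(viterbi_path_score(hmm, z, dp), oracle$score, tolerance = 1e-9)
  }
})

test_that("noiseless unfiltered signals decode to the exact sequence", {
  g <- pc_graph(4, 6, 3)
  m <- pc_model(4)
  s <- random_walk_sequence(g, 50, seed = 20)
  dw <- pmax(2L, sample_dwells(50 - 4 + 1, d = 8, seed = 21))  # dwells >= 2
  tr <- synthesize_signal(s, m, noise_sigma = 0, cutoff = Inf, dwells = dw)
  hmm <- build_hmm(g, m)
  path <- viterbi_path(hmm, tr)
  expect_identical(path_to_sequence(path, hmm$states), s)
})

test_that("path collapse emits one base per state change", {
  states <- c("ACGTAC", "CGTACA", "GTACAT")
  expect_equal(path_to_sequence(c(1, 1, 1), states), "ACGTAC")
  expect_equal(path_to_sequence(c(1, 1, 2, 2, 3), states), "ACGTACAT")
  long <- rep(1:3, each = 4)
  expect_equal(nchar(path_to_sequence(long, states)), 6 + 2)
})

test_that("basecall is deterministic and composes ISI mitigation", {
  g <- pc_graph(3, 4, 3)
  m <- pc_model(3)
  s <- random_walk_sequence(g, 40, seed = 22)
  tr <- synthesize_signal(s, m, noise_sigma = 1, cutoff = 950, seed = 23)
  b1 <- basecall(tr, g, m)
  b2 <- basecall(tr, g, m)
  expect_identical(b1, b2)
  # with mitigation the decoded sequence should be at least as close to truth
  # on a clean filtered step signal: spurious ramp samples are removed
  dw <- rep(8L, 38)
  tr2 <- synthesize_signal(s, m, noise_sigma = 0, cutoff = 950, dwells = dw)
  on <- basecall(tr2, g, m, isi = TRUE)
  off <- basecall(tr2, g, m, isi = FALSE)
  expect_lte(levenshtein_distance(on, s), levenshtein_distance(off, s))
})
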