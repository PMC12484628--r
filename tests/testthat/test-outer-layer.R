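test_that("RS is systematic and round-trips", {
  params <- rs_params(100, 80)
  expect_equal(params$t, 10)
  set.seed(24)
  msg <- sample(0:4095, 80)
  cw <- rs_encode(msg, params)
  expect_length(cw, 100)
  expect_identical(cw[1:80], msg)
  expect_identical(rs_decode(cw, params)$message, as.integer(msg))
  expect_error(rs_encode(msg[1:10], params), "k_rs")
  expect_error(rs_params(100, 79), "even")
})

test_that("t errors are corrected; t+1 never silently succeeds as correct", {
  params <- rs_params(100, 80)
  set.seed(25)
  msg <- sample(0:4095, 80)
  cw <- rs_encode(msg, params)
  for (trial in 1:50) {
    r <- cw
    pos <- sample(100, 10)
    r[pos] <- bitwXor(r[pos], sample(1:4095, 10, replace = TRUE))
    d <- rs_decode(r, params)
    expect_true(d$ok)
    expect_identical(d$message, as.integer(msg))
  }
  # beyond capacity: decoding either fails or returns a wrong message -- it is
  # never reported as a clean correction of the true message
  for (trial in 1:20) {
    r <- cw
    pos <- sample(100, 11)
    r[pos] <- bitwXor(r[pos], sample(1:4095, 11, replace = TRUE))
    d <- rs_decode(r, params)
    # either an explicit failure or a miscorrection to some other codeword;
    # a silent "success" equal to the true message would be a soundness bug
    expect_false(isTRUE(d$ok) && identical(d$message, as.integer(msg)))
  }
})

test_that("erasures decode up to n - k, mixed cases up to 2f + e <= n - k", {
  set.seed(26)
  msg <- sample(0:4095, 80)
  params <- rs_params(100, 80)
  cw <- rs_encode(msg, params)
  # n - k erasures, zero errors
  er <- sample(100, 20)
  r <- cw; r[er] <- 0
  d <- rs_decode(r, params, erasures = er)
  expect_true(d$ok)
  expect_identical(d$message, as.integer(msg))
  # f = 3 errors + e = 4 erasures with n - k = 10
  p2 <- rs_params(90, 80)
  cw2 <- rs_encode(msg, p2)
  for (trial in 1:10) {
    r <- cw2
    er <- sample(90, 4); r[er] <- 0
    ep <- sample(setdiff(1:90, er), 3)
    r[ep] <- bitwXor(r[ep], sample(1:4095, 3, replace = TRUE))
    d <- rs_decode(r, p2, erasures = er)
    expect_true(d$ok)
    expect_identical(d$message, as.integer(msg))
  }
  # too many erasures is flagged, not guessed
  er <- sample(90, 11)
  r <- cw2; r[er] <- 0
  expect_false(rs_decode(r, p2, erasures = er)$ok)
})

test_that("bit packing into 12-bit symbols is a big-endian identity", {
  expect_length(pack_bits(rep(0:1, 12)), 2)
  s13 <- pack_bits(c(rep(1L, 13)))
  expect_length(s13, 2)
  expect_equal(s13[2], bitwShiftL(1L, 11))  # 13th bit lands at the top of sym 2
  expect_identical(unpack_symbols(s13, 13), rep(1L, 13))
  set.seed(27)
  bits <- sample(0:1, 1e4, replace = TRUE)
  expect_identical(unpack_symbols(pack_bits(bits), length(bits)), as.integer(bits))
})

test_that("read filtering keeps only length-exact constraint-valid reads", {
  g <- pc_graph(3, 4, 3)
  r1 <- random_walk_sequence(g, 30, seed = 28)
  r2 <- random_walk_sequence(g, 30, seed = 29)
  expect_identical(filter_valid_reads(c(r1, r2), g, 30), c(r1, r2))
  broken <- paste0(substr(r1, 1, 10), "AAAA", substring(r1, 15))
  short <- substr(r1, 1, 29)
  expect_identical(filter_valid_reads(c(r1, broken, short, r2), g, 30), c(r1, r2))
  expect_length(filter_valid_reads(character(0), g, 30), 0)
})

test_that("majority consensus votes per position with fallback and abstain", {
  g <- pc_graph(3, 4, 3)
  r <- random_walk_sequence(g, 20, seed = 30)
  expect_identical(majority_consensus(c(r, r, r), g), r)
  expect_identical(majority_consensus(character(0), g), NA_character_)
  # plurality on a disagreeing position
  reads <- c("ACGT", "ACGT", "ACTT")
  expect_identical(majority_consensus(reads), "ACGT")
  # tie at a position resolves A < C < G < T
  expect_identical(majority_consensus(c("AAAA", "CAAA")), "AAAA")
  # constructed blend that violates the constraint -> most frequent whole read
  found <- NULL
  for (seed in 1:200) {
    a <- random_walk_sequence(g, 15, seed = seed)
    b <- random_walk_sequence(g, 15, seed = seed + 1000)
    c_ <- random_walk_sequence(g, 15, seed = seed + 2000)
    blend <- majority_consensus(c(a, b, c_))
    if (!check_sequence(g, blend)$valid) { found <- list(a, b, c_); break }
  }
  expect_false(is.null(found))
  cons <- majority_consensus(c(found[[1]], found[[2]], found[[3]]), g)
  expect_identical(cons, found[[1]])  # first occurring among equally frequent
  expect_equal(nchar(cons), 15)
})
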