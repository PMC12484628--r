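#' End-to-end storage pipeline
#'
#' `store()` turns a byte payload into constraint-satisfying DNA sequences:
#' bits -> 12-bit symbols -> one systematic RS codeword -> fixed-size bit
#' chunks -> state-split encoding -> constrained random padding. `retrieve()`
#' inverts the chain from simulated nanopore signals: Viterbi basecalling of
#' each read, padding removal, constraint filtering, majority consensus (a
#' failed sequence becomes an RS erasure), FSM decoding, RS decoding. At
#' delta = 0 the encoder is the trivial 2-bits-per-base map on unconstrained
#' sequences.
#'
#' @name pipeline
NULL

BASE_BITS <- list(A = c(0L, 0L), C = c(0L, 1L), G = c(1L, 0L), T = c(1L, 1L))

bits_to_bases <- function(bits) {
  stopifnot(length(bits) %% 2 == 0)
  m <- matrix(as.integer(bits), nrow = 2)
  paste(DNA_BASES[m[1, ] * 2 + m[2, ] + 1], collapse = "")
}

bases_to_bits <- function(seq) {
  code <- base_code(strsplit(seq, "", fixed = TRUE)[[1]])
  as.integer(rbind(code %/% 2, code %% 2))
}

#' Pipeline configuration
#'
#' Bundles the model and all channel/code parameters. Defaults follow the
#' standard operating point: 186-base sequences, 12/18-base pads, mean dwell
#' 8 samples, 4000 Hz sampling, 950 Hz cut-off, 1 pA noise.
#'
#' @param model a [kmer_model].
#' @param delta threshold in pA.
#' @param max_run homopolymer cap.
#' @param sequence_length unpadded sequence length in bases.
#' @param front_pad,back_pad pad lengths.
#' @param d expected dwell (samples); fs sampling rate (Hz); cutoff low-pass
#'   cut-off (Hz); noise_sigma noise sd (pA).
#' @param S reads per sequence.
#' @param rs_redundancy parity fraction for the RS outer code.
#' @param q_max encoder power bound.
#' @param seed master seed.
#' @param random_dwell draw geometric dwells in the simulator; `FALSE` gives
#'   the fully deterministic channel (fixed dwell `d`).
#' @param isi apply ISI mitigation when basecalling; default (`NULL`)
#'   mitigates exactly when the band-limiting filter is active
#'   (`is.finite(cutoff)`), since ISI is a filter artifact.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(model, delta = 4, max_run = 3, sequence_length = 186,
                            front_pad = 12, back_pad = 18, d = 8, fs = 4000,
                            cutoff = 950, noise_sigma = 1.0, S = 3,
                            rs_redundancy = 0.1, q_max = 6, seed = 1,
                            random_dwell = TRUE, isi = NULL) {
  stopifnot(inherits(model, "kmer_model"), sequence_length >= model$k,
            d > 1, fs > 0, cutoff > 0, S >= 1)
  if (is.null(isi)) isi <- is.finite(cutoff)
  structure(list(model = model, delta = delta, max_run = max_run,
                 sequence_length = sequence_length, front_pad = front_pad,
                 back_pad = back_pad, d = d, fs = fs, cutoff = cutoff,
                 noise_sigma = noise_sigma, S = S,
                 rs_redundancy = rs_redundancy, q_max = q_max,
                 seed = seed, random_dwell = random_dwell, isi = isi),
            class = "pipeline_config")
}

build_codec_for_config <- function(config) {
  if (config$delta == 0) {
    graph <- build_constrained_graph(config$model, delta = 0, max_run = Inf)
    list(graph = graph, fsm = NULL, p = 2L, q = 1L,
         n_words = config$sequence_length, k = config$model$k,
         seq_len = as.integer(config$sequence_length),
         bits_per_seq = 2L * config$sequence_length)
  } else {
    graph <- build_constrained_graph(config$model, delta = config$delta,
                                     max_run = config$max_run)
    fsm <- design_codec(graph, q_max = config$q_max)
    n_words <- (config$sequence_length - fsm$k) %/% fsm$q - fsm$flush_words
    if (n_words < 1) stop("sequence_length too short for this codec")
    list(graph = graph, fsm = fsm, p = fsm$p, q = fsm$q, n_words = n_words,
         k = fsm$k,
         seq_len = as.integer(fsm$k + fsm$q * (n_words + fsm$flush_words)),
         bits_per_seq = as.integer(fsm$p * n_words))
  }
}

#' Store a byte payload as DNA sequences
#'
#' @param payload raw vector (bytes) or integer 0/1 vector (bits).
#' @param config a [pipeline_config].
#' @param codec optional prebuilt codec (from an earlier call's `$codec`).
#' @return list with `sequences` (named character vector of padded
#'   sequences), `manifest`, and `codec` (graph + FSM for reuse).
#' @export
store <- function(payload, config, codec = NULL) {
  bits <- if (is.raw(payload)) as.integer(rawToBits(payload)) else as.integer(payload)
  stopifnot(length(bits) > 0, all(bits %in% c(0L, 1L)))
  if (is.null(codec)) codec <- build_codec_for_config(config)
  symbols <- pack_bits(bits)
  k_rs <- length(symbols)
  npar <- 2L * as.integer(ceiling(config$rs_redundancy * k_rs / 2))
  npar <- max(npar, 2L)
  if (k_rs + npar > 4095) {
    stop("payload too large for a single RS codeword over GF(2^12); chunk it upstream")
  }
  params <- rs_params(k_rs + npar, k_rs)
  codeword <- rs_encode(symbols, params)
  cbits <- unpack_symbols(codeword, 12L * params$n)
  n_seqs <- as.integer(ceiling(length(cbits) / codec$bits_per_seq))
  sequences <- character(n_seqs)
  entries <- vector("list", n_seqs)
  for (i in seq_len(n_seqs)) {
    lo <- (i - 1L) * codec$bits_per_seq + 1L
    hi <- min(i * codec$bits_per_seq, length(cbits))
    chunk <- c(cbits[lo:hi], integer(codec$bits_per_seq - (hi - lo + 1L)))
    if (is.null(codec$fsm)) {
      seq_i <- bits_to_bases(chunk)
      entry <- list(payload_bits = codec$bits_per_seq, pad_bits = 0L,
                    start_state = NA_integer_, sequence_length = codec$seq_len)
    } else {
      enc <- encode_bits(codec$fsm, chunk)
      seq_i <- enc$seq
      entry <- enc$entry
    }
    pad <- attach_padding(seq_i, codec$graph,
                          front_len = config$front_pad, back_len = config$back_pad,
                          seed = derive_seed(config$seed, i))
    entry$front_pad <- pad$front_pad
    entry$back_pad <- pad$back_pad
    sequences[i] <- pad$padded
    entries[[i]] <- entry
  }
  names(sequences) <- sprintf("seq_%d", seq_len(n_seqs))
  manifest <- list(
    k = codec$k, delta = config$delta, max_run = config$max_run,
    p = codec$p, q = codec$q, n_words = codec$n_words,
    sequence_length = codec$seq_len, bits_per_seq = codec$bits_per_seq,
    payload_bits = length(bits), codeword_bits = length(cbits),
    rs = list(n = params$n, k_rs = params$k_rs, t = params$t,
              prim_poly = params$prim_poly),
    seed = config$seed, n_sequences = n_seqs,
    sequences = entries)
  list(sequences = sequences, manifest = manifest, codec = codec)
}

#' Simulate reads for every stored sequence
#'
#' @param stored result of [store()].
#' @param config a [pipeline_config].
#' @return list (per sequence) of lists of `signal_trace`.
#' @export
simulate_stored <- function(stored, config) {
  lapply(seq_along(stored$sequences), function(i) {
    simulate_reads(stored$sequences[[i]], config$model, S = config$S,
                   seed = derive_seed(config$seed * 31L %% 97561L, i),
                   random_dwell = config$random_dwell %||% TRUE,
                   d = config$d, noise_sigma = config$noise_sigma,
                   cutoff = config$cutoff, fs = config$fs)
  })
}

#' Retrieve a payload from per-sequence signal sets
#'
#' @param signal_sets list (per sequence) of lists of `signal_trace`.
#' @param manifest the manifest produced by [store()].
#' @param config a [pipeline_config].
#' @param codec optional prebuilt codec (must match the manifest).
#' @return list with `payload` (raw bytes when `payload_bits` is a multiple
#'   of 8, else integer bits), `bits`, `ok` (RS success), and `report`
#'   (per-sequence status data.frame).
#' @export
retrieve <- function(signal_sets, manifest, config, codec = NULL) {
  if (is.null(codec)) codec <- build_codec_for_config(config)
  graph <- codec$graph
  hmm <- build_hmm(graph, config$model, d = config$d)
  n_seqs <- manifest$n_sequences
  stopifnot(length(signal_sets) == n_seqs)
  cbits <- integer(manifest$codeword_bits)
  erased_symbols <- integer(0)
  status <- character(n_seqs)
  for (i in seq_len(n_seqs)) {
    entry <- manifest$sequences[[i]]
    reads <- vapply(signal_sets[[i]], function(tr) {
      basecall(tr, graph, config$model, d = config$d, isi = config$isi, hmm = hmm)
    }, character(1))
    trimmed <- vapply(reads, function(r) {
      remove_padding(r, entry$front_pad, entry$sequence_length)$read
    }, character(1))
    valid <- filter_valid_reads(trimmed, graph, entry$sequence_length)
    cons <- majority_consensus(valid, graph)
    chunk <- NULL
    if (!is.na(cons)) {
      chunk <- tryCatch({
        if (is.null(codec$fsm)) {
          bases_to_bits(cons)
        } else {
          bits <- decode_sequence(codec$fsm, cons, entry)
          c(bits, integer(codec$bits_per_seq - length(bits)))
        }
      }, error = function(e) NULL)
    }
    lo <- (i - 1L) * codec$bits_per_seq + 1L
    hi <- min(i * codec$bits_per_seq, manifest$codeword_bits)
    if (is.null(chunk)) {
      sym_lo <- (lo - 1L) %/% 12L + 1L
      sym_hi <- (hi - 1L) %/% 12L + 1L
      erased_symbols <- c(erased_symbols, sym_lo:sym_hi)
      status[i] <- if (is.na(cons)) "erasure (no valid read)" else "erasure (decode failed)"
    } else {
      cbits[lo:hi] <- chunk[seq_len(hi - lo + 1L)]
      status[i] <- "ok"
    }
  }
  symbols <- pack_bits(cbits)[seq_len(manifest$rs$n)]
  params <- rs_params(manifest$rs$n, manifest$rs$k_rs)
  dec <- rs_decode(symbols, params, erasures = unique(erased_symbols))
  if (dec$ok) {
    bits <- unpack_symbols(dec$message, manifest$payload_bits)
  } else {
    bits <- unpack_symbols(symbols[seq_len(manifest$rs$k_rs)], manifest$payload_bits)
  }
  payload <- if (manifest$payload_bits %% 8 == 0) packBits(as.raw(bits)) else bits
  list(payload = payload, bits = bits, ok = dec$ok,
       report = data.frame(sequence = seq_len(n_seqs), status = status,
                           stringsAsFactors = FALSE),
       rs_status = dec$status)
}

#' Write sequences as FASTA / read them back
#'
#' @param sequences named character vector.
#' @param path file path.
#' @return `path` invisibly (write) / named character vector (read).
#' @export
write_fasta <- function(sequences, path) {
  ids <- names(sequences) %||% sprintf("seq_%d", seq_along(sequences))
  writeLines(as.vector(rbind(paste0(">", ids), unname(sequences))), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  names(seqs) <- ids
  seqs
}

#' Write / read a storage manifest as JSON
#'
#' @param manifest manifest list from [store()].
#' @param path file path.
#' @return `path` invisibly (write) / manifest list (read).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
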