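#' Finite-state encoders via state splitting
#'
#' The encoder maps p input bits to q output bases per step, walking a graph
#' derived from the q-th power of the constrained de Bruijn graph. The
#' construction follows the classic state-splitting recipe: pick (p, q) with
#' p/q <= cap(G), compute a non-negative integer approximate eigenvector x
#' with A_q x >= 2^p x, out-split states until every state has at least 2^p
#' outgoing edges, prune the excess edges (lowest weights first), and assign
#' the 2^p p-bit input words to the surviving edges in lexicographic label
#' order. When the all-ones vector (restricted to a subgraph) is already an
#' approximate eigenvector, no splitting is needed and the encoder is simply
#' the minimum-out-degree-2^p subgraph of G^q, which admits a plain
#' state-walking decoder.
#'
#' @name state_split_encoder
NULL

base_code <- function(ch) match(ch, DNA_BASES) - 1L

#' Convert packed integer labels to q-gram strings
#'
#' Labels on power-graph edges are base-4 packed (A=0, C=1, G=2, T=3, most
#' significant base first), so numeric order equals lexicographic order.
#'
#' @param x integer vector of packed labels.
#' @param q number of bases per label.
#' @return character vector.
#' @export
int_to_qgram <- function(x, q) {
  out <- character(length(x))
  chars <- matrix("", nrow = length(x), ncol = q)
  for (i in q:1) {
    chars[, i] <- DNA_BASES[x %% 4 + 1]
    x <- x %/% 4
  }
  apply(chars, 1, paste, collapse = "")
}

#' @rdname int_to_qgram
#' @param s character vector of q-grams.
#' @export
qgram_to_int <- function(s) {
  q <- nchar(s[1])
  vals <- vapply(strsplit(s, "", fixed = TRUE),
                 function(ch) sum((match(ch, DNA_BASES) - 1) * 4^((q - 1):0)),
                 numeric(1))
  as.integer(vals)
}

#' q-th power graph with emitted-base labels
#'
#' One edge per directed q-step path of the source graph, labeled with the q
#' bases emitted along the path (packed integers, see [int_to_qgram()]) and
#' weighted with the minimum single-step edge weight along the path -- the
#' weakest transition dominates segmentation risk.
#'
#' @param graph a `debruijn_graph`.
#' @param q number of steps (>= 1).
#' @return a `power_graph` (nodes shared with `graph`).
#' @export
power_graph <- function(graph, q) {
  stopifnot(q >= 1)
  n <- length(graph$nodes)
  last_code <- base_code(substr(graph$nodes, graph$k, graph$k))
  edge_by_from <- split(seq_along(graph$from), factor(graph$from, levels = seq_len(n)))
  outdeg <- lengths(edge_by_from)
  # start with 0-step paths (one per node), extend q times
  from <- seq_len(n)
  to <- seq_len(n)
  label <- integer(n)
  weight <- rep(Inf, n)
  for (step in seq_len(q)) {
    cnt <- outdeg[to]
    keep <- cnt > 0
    from <- rep(from[keep], cnt[keep])
    label <- rep(label[keep], cnt[keep])
    weight <- rep(weight[keep], cnt[keep])
    eidx <- unlist(edge_by_from[to[keep]], use.names = FALSE)
    to <- graph$to[eidx]
    label <- label * 4L + last_code[to]
    weight <- pmin(weight, graph$weight[eidx])
  }
  structure(list(k = graph$k, q = as.integer(q), nodes = graph$nodes,
                 from = from, to = to, label = as.integer(label),
                 weight = weight, graph = graph),
            class = "power_graph")
}

#' @export
print.power_graph <- function(x, ...) {
  cat(sprintf("power_graph: q=%d, %d nodes, %d q-step edges\n",
              x$q, length(x$nodes), length(x$from)))
  invisible(x)
}

#' Choose the encoder parameters (p, q)
#'
#' Over q in 1..q_max, sets p = floor(q * cap(G)) and returns the pair
#' maximizing the rate p/q, ties broken toward smaller q (cheaper splitting).
#' The feasibility condition p/q <= cap(G) always holds.
#'
#' @param graph a `debruijn_graph` with positive capacity.
#' @param q_max largest q considered (the splitting cost grows quickly in q).
#' @return list with `p`, `q`, `rate`, `capacity`.
#' @export
choose_pq <- function(graph, q_max = 6) {
  cap <- capacity(graph)
  if (cap <= 0) stop("capacity is 0: no encoder exists for this graph")
  pq_from_capacity(cap, q_max)
}

#' @rdname choose_pq
#' @param cap a capacity in bits/base.
#' @export
pq_from_capacity <- function(cap, q_max = 6) {
  qs <- seq_len(q_max)
  ps <- floor(qs * cap + 1e-9)   # guard against eigenvalue round-off at integers
  rates <- ps / qs
  ok <- ps >= 1
  if (!any(ok)) stop("capacity too small: floor(q*cap) < 1 for all q <= ", q_max)
  best_rate <- max(rates[ok])
  q <- min(qs[ok & abs(rates - best_rate) < 1e-12])
  list(p = as.integer(ps[q]), q = as.integer(q), rate = ps[q] / q, capacity = cap)
}

#' Approximate eigenvector for state splitting
#'
#' Finds a non-negative integer vector x with (A_q x)_i >= target * x_i for
#' every i with x_i > 0, by the Franaszek iteration
#' x <- min(x, floor(A_q x / target)) run to a fixed point from a constant
#' start vector. The start scale is the smallest power of two whose fixed
#' point is non-zero, so an all-ones solution (no splitting needed) is
#' preferred when one exists.
#'
#' @param pg a `power_graph`.
#' @param target required out-mass per unit weight, i.e. 2^p.
#' @param max_scale largest constant start value tried.
#' @return integer vector over the power-graph nodes (zeros mark dropped
#'   states).
#' @export
approximate_eigenvector <- function(pg, target, max_scale = 2^16) {
  n <- length(pg$nodes)
  apply_A <- function(x) {
    s <- rowsum(x[pg$to], pg$from)
    Ax <- numeric(n)
    Ax[as.integer(rownames(s))] <- s
    Ax
  }
  scale <- 1
  while (scale <= max_scale) {
    x <- rep(scale, n)
    for (it in seq_len(10000)) {
      nx <- pmin(x, floor(apply_A(x) / target))
      if (all(nx == x)) break
      x <- nx
    }
    if (any(x > 0)) return(as.integer(x))
    scale <- scale * 2
  }
  stop(sprintf("p/q infeasible on this graph: no approximate eigenvector for target %d", target))
}

#' Out-split states until min out-degree reaches 2^p
#'
#' Performs rounds of basic x-consistent out-splitting on the power graph:
#' a state u with x_u >= 2 is replaced by two descendants that partition u's
#' outgoing edges so that each part has destination x-mass at least
#' target * (descendant weight); incoming edges are duplicated to both
#' descendants. After at most sum(x) - #states rounds every state has weight
#' one and therefore out-degree (with multiplicity) >= target = 2^p.
#'
#' @param pg a `power_graph`.
#' @param x approximate eigenvector from [approximate_eigenvector()].
#' @param p input bits per step.
#' @return a `split_graph`: states (with parent node index) and labeled edges.
#' @export
state_split <- function(pg, x, p) {
  target <- 2^p
  keep <- which(x > 0)
  state_parent <- keep                       # state id -> original node index
  state_x <- as.numeric(x[keep])
  remap <- match(seq_along(pg$nodes), keep)
  sel <- pg$from %in% keep & pg$to %in% keep
  ef <- remap[pg$from[sel]]
  et <- remap[pg$to[sel]]
  el <- pg$label[sel]
  ew <- pg$weight[sel]

  partition_state <- function(u) {
    idx <- which(ef == u)
    masses <- state_x[et[idx]]
    ords <- list(order(-masses, el[idx], et[idx]),
                 order(masses, el[idx], et[idx]))
    W <- sum(masses)
    xu <- state_x[u]
    for (o in ords) {
      cum <- cumsum(masses[o])
      for (j in seq_len(length(idx) - 1)) {
        y1 <- min(xu - 1, floor(cum[j] / target))
        if (y1 >= 1 && (W - cum[j]) >= target * (xu - y1)) {
          return(list(part1 = idx[o[seq_len(j)]], part2 = idx[o[(j + 1):length(idx)]],
                      y1 = y1))
        }
      }
    }
    NULL
  }

  while (any(state_x >= 2)) {
    cand <- order(-state_x)
    cand <- cand[state_x[cand] >= 2]
    res <- NULL
    for (u in cand) {
      res <- partition_state(u)
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      stop("state splitting failed to find a consistent partition (invalid x?)")
    }
    xu <- state_x[u]
    new_id <- length(state_x) + 1L
    state_parent <- c(state_parent, state_parent[u])
    state_x[u] <- res$y1
    state_x <- c(state_x, xu - res$y1)
    # out-edges: part1 stays with u, part2 moves to the new descendant
    ef[res$part2] <- new_id
    # in-edges of u (including former self-loops) are duplicated to new_id
    into_u <- which(et == u)
    if (length(into_u) > 0) {
      ef <- c(ef, ef[into_u])
      et <- c(et, rep(new_id, length(into_u)))
      el <- c(el, el[into_u])
      ew <- c(ew, ew[into_u])
    }
  }
  structure(list(parent = state_parent, x = state_x, parent_nodes = pg$nodes,
                 from = ef, to = et, label = el, weight = ew, p = p, q = pg$q,
                 k = pg$k),
            class = "split_graph")
}

#' Prune excess edges down to out-degree exactly 2^p
#'
#' Per state, keeps the 2^p outgoing edges with the largest weight (the
#' minimum single-step current difference along the q-path); ties are broken
#' by keeping the lexicographically smaller q-gram label. When splitting has
#' produced several same-label edges (to sibling descendants), edges carrying
#' a label not yet kept are preferred so that the decoder faces as few label
#' duplicates as possible.
#'
#' @param sg a `split_graph` with min out-degree >= 2^p.
#' @param p input bits per step.
#' @return a `split_graph` with exactly 2^p out-edges per state.
#' @export
prune_excess_edges <- function(sg, p) {
  target <- 2^p
  n <- length(sg$parent)
  keep_idx <- integer(0)
  by_state <- split(seq_along(sg$from), factor(sg$from, levels = seq_len(n)))
  for (u in seq_len(n)) {
    idx <- by_state[[u]]
    if (length(idx) < target) {
      stop(sprintf("state %d has out-degree %d < 2^p = %d", u, length(idx), target))
    }
    o <- idx[order(-sg$weight[idx], sg$label[idx], sg$to[idx])]
    labs <- sg$label[o]
    first_of_label <- !duplicated(labs)
    ranked <- c(o[first_of_label], o[!first_of_label])
    keep_idx <- c(keep_idx, ranked[seq_len(target)])
  }
  structure(list(parent = sg$parent, x = sg$x, parent_nodes = sg$parent_nodes,
                 from = sg$from[keep_idx], to = sg$to[keep_idx],
                 label = sg$label[keep_idx], weight = sg$weight[keep_idx],
                 p = p, q = sg$q, k = sg$k),
            class = "split_graph")
}

#' Build the finite-state encoder
#'
#' Assigns the p-bit input words 0..2^p-1 to each state's outgoing edges in
#' lexicographic order of the q-gram labels (ties by destination state), and
#' fixes the start state as the one whose parent k-mer is lexicographically
#' smallest. The construction is fully deterministic.
#'
#' @param sg a pruned `split_graph` (out-degree exactly 2^p everywhere).
#' @param graph the source `debruijn_graph` (kept for constraint checks).
#' @return an `encoder_fsm`.
#' @export
build_encoder <- function(sg, graph = NULL) {
  p <- sg$p; q <- sg$q
  target <- 2^p
  n <- length(sg$parent)
  label_mat <- matrix(NA_integer_, n, target)
  to_mat <- matrix(NA_integer_, n, target)
  by_state <- split(seq_along(sg$from), factor(sg$from, levels = seq_len(n)))
  for (u in seq_len(n)) {
    idx <- by_state[[u]]
    o <- idx[order(sg$label[idx], sg$to[idx])]
    label_mat[u, ] <- sg$label[o]
    to_mat[u, ] <- sg$to[o]
  }
  parent_kmer <- sg$parent_nodes[sg$parent]
  start_state <- which(parent_kmer == min(parent_kmer))[1]
  anticipation <- fsm_anticipation(label_mat, to_mat)
  structure(list(p = as.integer(p), q = as.integer(q), k = as.integer(sg$k),
                 n_states = n, parent_kmer = parent_kmer,
                 label_mat = label_mat, to_mat = to_mat,
                 start_state = as.integer(start_state),
                 flush_words = as.integer(anticipation), graph = graph),
            class = "encoder_fsm")
}

# Decoder anticipation of the word assignment, by tracking pairs of distinct
# states reachable through identical label streams (Sardinas-Patterson style
# on the encoder graph). Splitting duplicates edge labels toward sibling
# descendant states, so a label may not pin down the next state; unique
# decodability requires every such ambiguous pair to die out (no common
# label continuations) within finitely many steps, never merging into the
# same state and never revisiting a pair (a revisit means a cycle, i.e.
# unbounded anticipation). Returns the number of lookahead words a decoder
# needs; 0 when all labels are distinct per state (plain state walking).
fsm_anticipation <- function(label_mat, to_mat, max_pairs = 50000) {
  n <- nrow(label_mat)
  pair_key <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  frontier <- integer(0)
  for (s in seq_len(n)) {
    labs <- label_mat[s, ]
    if (anyDuplicated(labs)) {
      for (L in unique(labs[duplicated(labs)])) {
        tos <- unique(to_mat[s, labs == L])
        if (length(tos) < sum(labs == L)) {
          stop("encoder not uniquely decodable: duplicate (label, next-state) edge")
        }
        cmb <- utils::combn(tos, 2)
        frontier <- c(frontier, pair_key(cmb[1, ], cmb[2, ]))
      }
    }
  }
  frontier <- unique(frontier)
  if (length(frontier) == 0) return(0L)
  seen <- frontier
  depth <- 0L
  while (length(frontier) > 0) {
    depth <- depth + 1L
    nxt <- integer(0)
    for (key in frontier) {
      a <- key %/% (n + 1); b <- key %% (n + 1)
      la <- split(to_mat[a, ], label_mat[a, ])
      lb <- split(to_mat[b, ], label_mat[b, ])
      for (L in intersect(names(la), names(lb))) {
        for (ta in la[[L]]) for (tb in lb[[L]]) {
          if (ta == tb) {
            stop("encoder not uniquely decodable: ambiguous paths merge")
          }
          nxt <- c(nxt, pair_key(ta, tb))
        }
      }
    }
    nxt <- unique(nxt)
    if (any(nxt %in% seen)) {
      stop("encoder not uniquely decodable: ambiguous state pairs cycle")
    }
    seen <- c(seen, nxt)
    if (length(seen) > max_pairs) {
      stop("encoder decodability check exceeded pair budget")
    }
    frontier <- nxt
  }
  depth
}

#' @export
print.encoder_fsm <- function(x, ...) {
  cat(sprintf("encoder_fsm: (p,q)=(%d,%d), rate %.3f bits/base, %d states, start %s\n",
              x$p, x$q, x$p / x$q, x$n_states, x$parent_kmer[x$start_state]))
  invisible(x)
}

#' Design a codec for a constrained graph
#'
#' Convenience wrapper running the whole construction: (p, q) selection
#' (unless given), power graph, approximate eigenvector, state splitting,
#' excess-edge pruning, and word assignment.
#'
#' @param graph a `debruijn_graph`.
#' @param p,q encoder parameters; when NULL the best feasible rate is found
#'   by searching the (p, q) grid.
#' @param q_max largest q considered.
#' @param split_budget largest number of state-splitting rounds attempted for
#'   a candidate before moving on (keeps construction time bounded).
#' @return an `encoder_fsm`.
#' @export
design_codec <- function(graph, p = NULL, q = NULL, q_max = 6,
                         split_budget = 300) {
  pg_cache <- vector("list", max(q_max, q %||% 0))
  get_pg <- function(q) {
    if (is.null(pg_cache[[q]])) pg_cache[[q]] <<- power_graph(graph, q)
    pg_cache[[q]]
  }
  build_one <- function(p, q) {
    pg <- get_pg(q)
    x <- approximate_eigenvector(pg, 2^p)
    if (sum(x) - sum(x > 0) > split_budget) {
      stop(sprintf("(p,q)=(%d,%d) needs %d splitting rounds (> budget %d)",
                   p, q, sum(x) - sum(x > 0), split_budget))
    }
    sg <- state_split(pg, x, p)
    sg <- prune_excess_edges(sg, p)
    build_encoder(sg, graph)
  }
  if (!is.null(p) && !is.null(q)) return(build_one(p, q))
  # full (p, q) grid under the capacity bound, best rate first (ties: smaller
  # q). Candidates drop out when their approximate eigenvector forces more
  # splitting than the budget allows or when the pruned split graph is not
  # uniquely decodable; the next-best rate is then tried.
  cap <- capacity(graph)
  if (cap <= 0) stop("capacity is 0: no encoder exists for this graph")
  cand <- do.call(rbind, lapply(seq_len(q_max), function(qq) {
    pmaxq <- floor(qq * cap + 1e-9)
    if (pmaxq < 1) return(NULL)
    data.frame(q = qq, p = seq_len(pmaxq))
  }))
  cand <- cand[order(-(cand$p / cand$q), cand$q), ]
  last_err <- NULL
  for (i in seq_len(nrow(cand))) {
    fsm <- tryCatch(build_one(cand$p[i], cand$q[i]), error = function(e) e)
    if (!inherits(fsm, "error")) return(fsm)
    last_err <- fsm
  }
  stop("no feasible uniquely-decodable encoder found up to q_max = ", q_max,
       " (last error: ", conditionMessage(last_err), ")")
}

bits_to_words <- function(bits, p) {
  stopifnot(length(bits) %% p == 0)
  m <- matrix(bits, nrow = p)
  as.integer(colSums(m * 2^((p - 1):0)))
}

words_to_bits <- function(words, p) {
  out <- integer(length(words) * p)
  for (i in seq_len(p)) {
    out[seq(i, by = p, length.out = length(words))] <-
      (words %/% 2^(p - i)) %% 2
  }
  as.integer(out)
}

#' Encode a bit payload into a DNA sequence
#'
#' Zero-pads the payload to a multiple of p, then walks the FSM from its
#' start state, emitting one q-gram per p-bit word, then appending the
#' encoder's termination flush (`flush_words` all-zero words, non-zero only
#' for encoders that required genuine state splitting). The output is the
#' start state's parent k-mer followed by the emitted q-grams, and always
#' satisfies the source graph constraint.
#' Total length: k + q * (ceil(|bits| / p) + flush_words).
#'
#' @param fsm an `encoder_fsm`.
#' @param bits integer vector of 0/1.
#' @return list with `seq` (DNA string) and `entry` (manifest record:
#'   `payload_bits`, `pad_bits`, `start_state`, `sequence_length`).
#' @export
encode_bits <- function(fsm, bits) {
  bits <- as.integer(bits)
  stopifnot(all(bits %in% c(0L, 1L)))
  pad_bits <- (fsm$p - length(bits) %% fsm$p) %% fsm$p
  padded <- c(bits, integer(pad_bits))
  words <- if (length(padded) > 0) bits_to_words(padded, fsm$p) else integer(0)
  # termination flush: encoders built with genuine splitting need
  # `flush_words` lookahead words so the decoder can pin down the payload
  words <- c(words, integer(fsm$flush_words))
  state <- fsm$start_state
  labels <- integer(length(words))
  for (i in seq_along(words)) {
    w <- words[i] + 1L
    labels[i] <- fsm$label_mat[state, w]
    state <- fsm$to_mat[state, w]
  }
  seq <- paste0(fsm$parent_kmer[fsm$start_state],
                paste(int_to_qgram(labels, fsm$q), collapse = ""))
  list(seq = seq,
       entry = list(payload_bits = length(bits), pad_bits = pad_bits,
                    start_state = fsm$start_state,
                    sequence_length = fsm$k + fsm$q * length(words)))
}

#' Decode a DNA sequence back to bits
#'
#' Walks the FSM from the recorded start state, matching successive q-grams
#' against the current state's outgoing edges and inverting the word
#' assignment. When the construction required genuine state splitting, a
#' label may be carried by several edges of a state (to sibling descendants);
#' the decoder then tracks every label-consistent state path -- the
#' state-splitting construction guarantees bounded anticipation, so all
#' surviving paths agree on the decoded words (asserted).
#'
#' @param fsm an `encoder_fsm`.
#' @param seq DNA string starting with the start state's parent k-mer.
#' @param entry manifest record from [encode_bits()].
#' @return integer vector of payload bits.
#' @export
decode_sequence <- function(fsm, seq, entry) {
  k <- fsm$k; q <- fsm$q; p <- fsm$p
  start <- entry$start_state %||% fsm$start_state
  prefix <- substr(seq, 1, k)
  if (prefix != fsm$parent_kmer[start]) {
    stop("constraint-violating read: sequence does not start with the start-state k-mer")
  }
  body <- substring(seq, k + 1)
  nb <- nchar(body)
  if (nb %% q != 0) stop("incomplete block: body length ", nb, " not a multiple of q=", q)
  n_blocks <- nb %/% q
  blocks <- if (n_blocks > 0) {
    qgram_to_int(substring(body, seq(1, nb, by = q), seq(q, nb, by = q)))
  } else integer(0)
  cand_states <- start
  cand_words <- list(integer(0))
  for (b in seq_len(n_blocks)) {
    new_states <- integer(0)
    new_words <- list()
    for (ci in seq_along(cand_states)) {
      s <- cand_states[ci]
      hit <- which(fsm$label_mat[s, ] == blocks[b])
      for (h in hit) {
        new_states <- c(new_states, fsm$to_mat[s, h])
        new_words[[length(new_words) + 1]] <- c(cand_words[[ci]], h - 1L)
      }
    }
    if (length(new_states) == 0) {
      stop(sprintf("constraint-violating read at block %d (q-gram %s not on any out-edge)",
                   b, int_to_qgram(blocks[b], q)))
    }
    # merge identical (state, word-history) candidates
    keyify <- vapply(seq_along(new_states),
                     function(i) paste(new_states[i], paste(new_words[[i]], collapse = ",")),
                     character(1))
    keep <- !duplicated(keyify)
    cand_states <- new_states[keep]
    cand_words <- new_words[keep]
    if (length(cand_states) > 4096) stop("decoder candidate set exploded (corrupt FSM?)")
  }
  n_payload <- entry$payload_bits %||% (length(cand_words[[1]]) * p)
  npw <- as.integer(ceiling(n_payload / p))   # payload words; the rest is flush
  payload_words <- lapply(cand_words, function(w) w[seq_len(min(npw, length(w)))])
  word_strings <- unique(vapply(payload_words, paste, character(1), collapse = ","))
  if (length(word_strings) > 1) {
    stop("ambiguous decode: surviving state paths disagree on payload words")
  }
  bits <- words_to_bits(payload_words[[1]], p)
  bits[seq_len(min(n_payload, length(bits)))]
}

#' Attach constrained random padding
#'
#' Prepends `front_len` and appends `back_len` random bases obtained by
#' seeded random walks on the constrained graph (a reverse walk ending at the
#' sequence's first k-mer and a forward walk from its last k-mer), so the
#' padded whole still satisfies the constraint. Pads are recorded so decoding
#' can strip them.
#'
#' @param seq constraint-valid DNA string.
#' @param graph the `debruijn_graph`.
#' @param front_len,back_len pad lengths in bases.
#' @param seed integer seed.
#' @param max_tries retries with derived seeds if a walk dead-ends.
#' @return list with `padded`, `front_pad`, `back_pad`.
#' @export
attach_padding <- function(seq, graph, front_len = 12, back_len = 18, seed = 1,
                           max_tries = 50) {
  k <- graph$k
  n <- length(graph$nodes)
  out_by_from <- split(seq_along(graph$from), factor(graph$from, levels = seq_len(n)))
  in_by_to <- split(seq_along(graph$from), factor(graph$to, levels = seq_len(n)))
  first_kmer <- substr(seq, 1, k)
  last_kmer <- substring(seq, nchar(seq) - k + 1)
  i_first <- match(first_kmer, graph$nodes)
  i_last <- match(last_kmer, graph$nodes)
  if (is.na(i_first) || is.na(i_last)) stop("sequence endpoints are not graph nodes")
  for (try in seq_len(max_tries)) {
    res <- withr::with_seed(as.integer(seed) + (try - 1L), {
      front <- character(0)
      cur <- i_first
      ok <- TRUE
      for (i in seq_len(front_len)) {
        es <- in_by_to[[cur]]
        if (length(es) == 0) { ok <- FALSE; break }
        e <- if (length(es) == 1) es else es[sample.int(length(es), 1)]
        cur <- graph$from[e]
        front <- c(substr(graph$nodes[cur], 1, 1), front)
      }
      back <- character(0)
      cur <- i_last
      if (ok) for (i in seq_len(back_len)) {
        es <- out_by_from[[cur]]
        if (length(es) == 0) { ok <- FALSE; break }
        e <- if (length(es) == 1) es else es[sample.int(length(es), 1)]
        cur <- graph$to[e]
        back <- c(back, substr(graph$nodes[cur], k, k))
      }
      list(ok = ok, front = paste(front, collapse = ""), back = paste(back, collapse = ""))
    })
    if (res$ok) {
      padded <- paste0(res$front, seq, res$back)
      chk <- check_sequence(graph, padded)
      if (chk$valid) {
        return(list(padded = padded, front_pad = res$front, back_pad = res$back))
      }
    }
  }
  stop("could not construct constrained padding after ", max_tries, " tries")
}

#' Remove padding from a basecalled read
#'
#' Locates the recorded front pad within the first `front_len + slack` bases
#' at minimal edit distance (earliest end position on ties), cuts through it,
#' and trims the tail to the recorded sequence length when the remainder is
#' longer. Reads whose best front-pad match exceeds edit distance `slack` are
#' flagged as unanchored but still trimmed best-effort.
#'
#' @param read basecalled DNA string.
#' @param front_pad the recorded front pad.
#' @param sequence_length the unpadded sequence length in bases.
#' @param slack edit-distance / position slack (default 6).
#' @return list with `read` (trimmed), `anchored` (logical), `distance`.
#' @export
remove_padding <- function(read, front_pad, sequence_length, slack = 6) {
  fl <- nchar(front_pad)
  ends <- max(0, fl - slack):min(nchar(read), fl + slack)
  best_e <- ends[1]; best_d <- Inf
  for (e in ends) {
    d <- levenshtein_distance(substr(read, 1, e), front_pad)
    if (d < best_d) { best_d <- d; best_e <- e }
  }
  trimmed <- substring(read, best_e + 1)
  if (nchar(trimmed) > sequence_length) {
    trimmed <- substr(trimmed, 1, sequence_length)
  }
  list(read = trimmed, anchored = best_d <= slack, distance = best_d)
}

#' Serialize an encoder to a diagnostic JSON file
#'
#' @param fsm an `encoder_fsm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
fsm_to_json <- function(fsm, path) {
  obj <- list(p = fsm$p, q = fsm$q, k = fsm$k, start_state = fsm$start_state,
              states = lapply(seq_len(fsm$n_states), function(s) {
                list(parent_kmer = fsm$parent_kmer[s],
                     labels = int_to_qgram(fsm$label_mat[s, ], fsm$q),
                     to = fsm$to_mat[s, ])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
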