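#' Constrained de Bruijn graphs
#'
#' Vertices are k-mers; an edge u -> v exists when v is u shifted left by one
#' base (overlap in k-1 symbols). Each edge carries the absolute difference
#' |mu_u - mu_v| of the mean current levels of its endpoint k-mers. The code
#' constraint prunes edges whose level difference does not exceed the
#' threshold `delta` (in pA) and removes k-mers containing a homopolymer run
#' longer than `max_run`. After pruning, the graph is restricted to its best
#' strongly connected component so that capacity and encoder construction are
#' well defined.
#'
#' @name debruijn_graph
NULL

longest_run <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

new_debruijn_graph <- function(k, delta, max_run, nodes, from, to, weight, mean_pA) {
  structure(
    list(k = as.integer(k), delta = delta, max_run = max_run,
         nodes = nodes, from = as.integer(from), to = as.integer(to),
         weight = as.numeric(weight), mean_pA = mean_pA),
    class = "debruijn_graph"
  )
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf("debruijn_graph: k=%d, delta=%g pA, max_run=%s, %d nodes, %d edges\n",
              x$k, x$delta, format(x$max_run), length(x$nodes), length(x$from)))
  invisible(x)
}

graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  Matrix::sparseMatrix(i = graph$from, j = graph$to, x = 1,
                       dims = c(n, n))
}

#' Build the delta- and run-length-constrained de Bruijn graph
#'
#' Enumerates all de Bruijn transitions between retained k-mers, labels each
#' with |mu_u - mu_v| from `model`, prunes edges with weight <= `delta`
#' (for `delta > 0`; `delta = 0` means unconstrained and keeps every overlap
#' edge, including zero-weight ones), deletes nodes whose k-mer contains a
#' homopolymer run longer than `max_run`, and restricts the result to the
#' strongly connected component with the largest Perron eigenvalue.
#'
#' @param model a [kmer_model].
#' @param delta current-difference threshold in pA (>= 0).
#' @param max_run maximum allowed homopolymer run length (`Inf` for none).
#' @return a `debruijn_graph`.
#' @export
build_constrained_graph <- function(model, delta = 0, max_run = 3) {
  stopifnot(inherits(model, "kmer_model"), delta >= 0, max_run >= 1)
  k <- model$k
  nodes <- model$kmers
  if (is.finite(max_run) && max_run < k) {
    runs <- vapply(nodes, longest_run, numeric(1))
    nodes <- nodes[runs <= max_run]
  }
  if (length(nodes) == 0) stop("constraint infeasible: no k-mer satisfies max_run=", max_run)
  mu <- unname(model$mean_pA[nodes])
  idx <- seq_along(nodes)
  suffix <- substr(nodes, 2, k)
  from <- integer(0); to <- integer(0)
  for (base in DNA_BASES) {
    v <- paste0(suffix, base)
    j <- match(v, nodes)
    keep <- !is.na(j)
    from <- c(from, idx[keep])
    to <- c(to, j[keep])
  }
  weight <- abs(mu[from] - mu[to])
  if (delta > 0) {
    keep <- weight > delta
    from <- from[keep]; to <- to[keep]; weight <- weight[keep]
  }
  if (length(from) == 0) {
    stop(sprintf("constraint infeasible at delta=%g pA: no edges survive", delta))
  }
  g <- largest_irreducible_subgraph(nodes, from, to, weight,
                                    k = k, delta = delta, max_run = max_run)
  g$mean_pA <- model$mean_pA[g$nodes]
  g
}

#' Restrict to the best strongly connected component
#'
#' Given a de Bruijn-consistent node/edge set, returns the induced subgraph of
#' the strongly connected component whose adjacency matrix has the largest
#' Perron eigenvalue (ties broken toward the component containing the
#' lexicographically smallest k-mer). Components without any edge are ignored.
#'
#' @param nodes character vector of k-mers.
#' @param from,to integer edge endpoints (indices into `nodes`).
#' @param weight numeric edge weights (pA).
#' @param k,delta,max_run metadata stored on the result.
#' @return a `debruijn_graph`.
#' @export
largest_irreducible_subgraph <- function(nodes, from, to, weight,
                                         k = nchar(nodes[1]), delta = NA, max_run = NA) {
  n <- length(nodes)
  ig <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  comp <- igraph::components(ig, mode = "strong")$membership
  # a component is usable only if it contains at least one edge
  has_edge <- unique(comp[from][comp[from] == comp[to]])
  if (length(has_edge) == 0) {
    stop("constraint infeasible: no strongly connected component with an edge")
  }
  best <- NULL; best_lambda <- -Inf; best_key <- NULL
  for (cid in has_edge) {
    keep_nodes <- which(comp == cid)
    sel <- from %in% keep_nodes & to %in% keep_nodes
    remap <- match(seq_len(n), keep_nodes)
    f2 <- remap[from[sel]]; t2 <- remap[to[sel]]
    lambda <- perron_eigenvalue(f2, t2, length(keep_nodes))
    key <- min(nodes[keep_nodes])
    if (lambda > best_lambda + 1e-12 ||
        (abs(lambda - best_lambda) <= 1e-12 && !is.null(best_key) && key < best_key)) {
      best_lambda <- lambda
      best_key <- key
      best <- list(nodes = keep_nodes, sel = sel, remap = remap)
    }
  }
  sub_nodes <- nodes[best$nodes]
  ord <- order(sub_nodes)
  rank_in_sorted <- match(seq_along(best$nodes), ord)
  f <- rank_in_sorted[best$remap[from[best$sel]]]
  t_ <- rank_in_sorted[best$remap[to[best$sel]]]
  new_debruijn_graph(k, delta, max_run, sub_nodes[ord], f, t_, weight[best$sel],
                     mean_pA = NULL)
}

# Perron (largest) eigenvalue of a non-negative 0/1 adjacency by power
# iteration on A + I (primitive for irreducible A, so convergence is
# guaranteed even for periodic graphs); relative tolerance 1e-10.
perron_eigenvalue <- function(from, to, n, tol = 1e-10, max_iter = 1e5) {
  if (length(from) == 0) return(0)
  A <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x   # (A + I) x: primitive, so ratios converge
    r <- y / x                     # Collatz-Wielandt: min(r) <= lambda+1 <= max(r)
    if (max(r) - min(r) <= tol * max(r)) {
      return((max(r) + min(r)) / 2 - 1)
    }
    x <- y / max(y)
  }
  warning("power iteration did not reach tolerance; returning last estimate")
  max(y) - 1
}

#' Capacity of a constrained graph
#'
#' The capacity cap(G) is log2 of the Perron eigenvalue of the adjacency
#' matrix: the maximum number of data bits per base carried by long paths of
#' G. An unpruned de Bruijn graph is 4-out-regular, so its capacity is exactly
#' 2 bits/base; a bare cycle has capacity 0.
#'
#' @param graph a `debruijn_graph` (non-empty, irreducible).
#' @return capacity in bits per base, in `[0, 2]`.
#' @export
capacity <- function(graph) {
  stopifnot(inherits(graph, "debruijn_graph"))
  if (length(graph$from) == 0) stop("capacity undefined: graph has no edges")
  lambda <- perron_eigenvalue(graph$from, graph$to, length(graph$nodes))
  log2(lambda)
}

#' Check a sequence against the graph constraint
#'
#' A sequence is valid when every length-k window is a retained k-mer and
#' every adjacent window pair is an edge of the graph.
#'
#' @param graph a `debruijn_graph`.
#' @param seq a DNA string of length >= k.
#' @return list with `valid` (logical) and `position`: NA when valid,
#'   otherwise the 1-based base position where the first violation occurs
#'   (the start of the offending window, or the position of the base that
#'   breaks an edge).
#' @export
check_sequence <- function(graph, seq) {
  k <- graph$k
  m <- nchar(seq)
  if (m < k) stop("sequence shorter than k")
  wins <- substring(seq, 1:(m - k + 1), k:m)
  node_idx <- match(wins, graph$nodes)
  bad_node <- if (anyNA(node_idx)) which(is.na(node_idx))[1] else Inf
  bad_pair <- Inf
  if (length(node_idx) > 1) {
    key <- paste(node_idx[-length(node_idx)], node_idx[-1])
    ok <- key %in% paste(graph$from, graph$to)
    ok[is.na(node_idx[-length(node_idx)]) | is.na(node_idx[-1])] <- TRUE
    if (!all(ok)) bad_pair <- which(!ok)[1] + k
  }
  p <- min(bad_node, bad_pair)
  if (is.finite(p)) return(list(valid = FALSE, position = as.integer(p)))
  list(valid = TRUE, position = NA_integer_)
}

# ---- exact path counting (big-integer accumulator) -------------------------

BIG_BASE <- 1e7

big_from_int <- function(x) {
  if (x == 0) return(0)
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- x %/% BIG_BASE
  }
  limbs
}

big_add <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- max(la, lb)
  out <- numeric(n + 1)
  out[seq_len(la)] <- a
  out[seq_len(lb)] <- out[seq_len(lb)] + b
  for (i in seq_len(n)) {
    if (out[i] >= BIG_BASE) {
      out[i + 1] <- out[i + 1] + out[i] %/% BIG_BASE
      out[i] <- out[i] %% BIG_BASE
    }
  }
  if (out[n + 1] == 0) out <- out[seq_len(n)]
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_to_double <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))

big_to_string <- function(a) {
  a <- rev(a)
  paste0(format(a[1], scientific = FALSE),
         paste(sprintf("%07d", a[-1]), collapse = ""))
}

#' Count directed paths of a given edge length
#'
#' Computes `1^T A^length 1` (number of directed walks with `length` edges)
#' in exact integer arithmetic, so counts stay exact beyond 2^53.
#'
#' @param graph a `debruijn_graph`.
#' @param length number of edges in each counted path (>= 0).
#' @param as to return a `"double"` (possibly rounded for huge counts) or a
#'   decimal `"string"` (exact).
#' @return the count.
#' @export
count_paths <- function(graph, length, as = c("double", "string")) {
  as <- match.arg(as)
  stopifnot(length >= 0)
  n <- length(graph$nodes)
  adj <- split(graph$to, factor(graph$from, levels = seq_len(n)))
  v <- rep(list(big_from_int(1)), n)
  if (length > 0) {
    for (step in seq_len(length)) {
      nv <- vector("list", n)
      for (u in seq_len(n)) {
        targets <- adj[[u]]
        acc <- 0
        for (t_ in targets) acc <- big_add(acc, v[[t_]])
        nv[[u]] <- acc
      }
      v <- nv
    }
  }
  total <- 0
  for (u in seq_len(n)) total <- big_add(total, v[[u]])
  if (identical(total, 0)) total <- numeric(1)
  if (as == "double") big_to_double(total) else big_to_string(total)
}

#' Export the edge list
#'
#' @param graph a `debruijn_graph`.
#' @param path optional TSV path (columns u, v, weight_pA); when NULL a
#'   data.frame is returned instead.
#' @return data.frame (invisibly when written to file).
#' @export
graph_edges <- function(graph, path = NULL) {
  df <- data.frame(u = graph$nodes[graph$from], v = graph$nodes[graph$to],
                   weight_pA = graph$weight, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Random constrained sequence by graph walk
#'
#' Uniform random walk on the graph, emitting the start k-mer and one base per
#' step. Used for the unconstrained baseline and for padding.
#'
#' @param graph a `debruijn_graph`.
#' @param length total sequence length in bases (>= k).
#' @param seed optional integer seed.
#' @param start_node optional start node index (default: uniform).
#' @return a DNA string that passes [check_sequence()].
#' @export
random_walk_sequence <- function(graph, length, seed = NULL, start_node = NULL) {
  stopifnot(length >= graph$k)
  run <- function() {
    n <- length(graph$nodes)
    adj <- split(seq_along(graph$from), factor(graph$from, levels = seq_len(n)))
    cur <- if (is.null(start_node)) sample.int(n, 1) else start_node
    out <- graph$nodes[cur]
    steps <- length - graph$k
    if (steps > 0) {
      for (i in seq_len(steps)) {
        es <- adj[[cur]]
        e <- if (length(es) == 1) es else es[sample.int(length(es), 1)]
        cur <- graph$to[e]
        out <- c(out, substr(graph$nodes[cur], graph$k, graph$k))
      }
    }
    paste(out, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
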