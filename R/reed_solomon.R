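#' Reed-Solomon outer code over GF(2^12)
#'
#' Systematic RS codes on 12-bit symbols (codeword length up to 4095),
#' correcting t = (n - k)/2 symbol errors, or f errors plus e erasures
#' whenever 2f + e <= n - k. Field arithmetic uses exp/log tables over the
#' primitive polynomial x^12 + x^6 + x^4 + x + 1 (0x1053); generator roots
#' are alpha^1 .. alpha^(n-k). Decoding is Berlekamp-Massey with erasure
#' initialization, Chien search, and the Forney algorithm.
#'
#' @name reed_solomon
NULL

GF_M <- 12L
GF_SIZE <- 4096L
GF_PRIM_POLY <- 0x1053L

.gf <- new.env(parent = emptyenv())

gf_tables <- function() {
  if (is.null(.gf$exp)) {
    expt <- integer(2 * (GF_SIZE - 1))
    logt <- integer(GF_SIZE)
    a <- 1L
    for (i in 0:(GF_SIZE - 2)) {
      expt[i + 1] <- a
      logt[a + 1] <- i
      a <- bitwShiftL(a, 1)
      if (bitwAnd(a, GF_SIZE) != 0) a <- bitwXor(a, GF_PRIM_POLY)
    }
    if (a != 1L) stop("0x1053 is not primitive over GF(2^12)?")  # period check
    expt[GF_SIZE:(2 * (GF_SIZE - 1))] <- expt[1:(GF_SIZE - 1)]
    .gf$exp <- expt
    .gf$log <- logt
  }
  .gf
}

gf_mul <- function(x, y) {
  g <- gf_tables()
  out <- integer(max(length(x), length(y)))
  x <- rep_len(as.integer(x), length(out))
  y <- rep_len(as.integer(y), length(out))
  nz <- x != 0L & y != 0L
  out[nz] <- g$exp[g$log[x[nz] + 1] + g$log[y[nz] + 1] + 1]
  out
}

gf_div <- function(x, y) {
  g <- gf_tables()
  if (any(y == 0)) stop("division by zero in GF(2^12)")
  out <- integer(max(length(x), length(y)))
  x <- rep_len(as.integer(x), length(out))
  y <- rep_len(as.integer(y), length(out))
  nz <- x != 0L
  out[nz] <- g$exp[(g$log[x[nz] + 1] - g$log[y[nz] + 1]) %% (GF_SIZE - 1) + 1]
  out
}

gf_pow <- function(i) {
  g <- gf_tables()
  g$exp[(as.integer(i) %% (GF_SIZE - 1)) + 1]
}

gf_inv <- function(x) gf_div(1L, x)

# polynomials as ascending-order integer vectors: p[1] = x^0 coefficient
poly_trim <- function(p) {
  while (length(p) > 1 && p[length(p)] == 0L) p <- p[-length(p)]
  p
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  av <- integer(n); av[seq_along(a)] <- a
  bv <- integer(n); bv[seq_along(b)] <- b
  poly_trim(bitwXor(av, bv))
}

poly_scale <- function(p, c) gf_mul(p, rep(c, length(p)))

poly_mul <- function(a, b) {
  out <- integer(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    if (a[i] != 0L) {
      out[i:(i + length(b) - 1)] <- bitwXor(out[i:(i + length(b) - 1)],
                                            gf_mul(rep(a[i], length(b)), b))
    }
  }
  poly_trim(out)
}

poly_eval <- function(p, x) {   # Horner, ascending order
  acc <- 0L
  for (i in length(p):1) acc <- bitwXor(gf_mul(acc, x), p[i])
  acc
}

#' RS code parameters
#'
#' @param n codeword length in symbols (<= 4095).
#' @param k_rs message length in symbols; n - k_rs must be even (t = (n-k)/2).
#' @return an `rs_params` list (n, k_rs, t, prim_poly).
#' @export
rs_params <- function(n, k_rs) {
  stopifnot(k_rs >= 1, k_rs < n, n <= GF_SIZE - 1)
  if ((n - k_rs) %% 2 != 0) stop("n - k_rs must be even")
  structure(list(n = as.integer(n), k_rs = as.integer(k_rs),
                 t = as.integer((n - k_rs) / 2), prim_poly = GF_PRIM_POLY),
            class = "rs_params")
}

rs_generator <- function(nparity) {
  g <- 1L
  for (i in seq_len(nparity)) g <- poly_mul(g, c(gf_pow(i), 1L))  # (alpha^i + x)
  g
}

#' Systematic RS encoding
#'
#' @param message integer vector of `k_rs` symbols in 0..4095.
#' @param params an [rs_params].
#' @return codeword of `n` symbols; message verbatim in positions 1..k_rs.
#' @export
rs_encode <- function(message, params) {
  message <- as.integer(message)
  if (length(message) != params$k_rs) {
    stop("message must have exactly k_rs = ", params$k_rs, " symbols")
  }
  stopifnot(all(message >= 0 & message < GF_SIZE))
  npar <- params$n - params$k_rs
  gen <- rs_generator(npar)                     # ascending, degree npar
  # long division of m(x) * x^npar by g(x); work in descending order
  rem <- integer(npar)
  for (s in message) {
    coef <- bitwXor(s, rem[1])
    rem <- c(rem[-1], 0L)
    if (coef != 0L) {
      # subtract coef * g(x) (monic, descending coeffs gen[npar:1] after lead)
      rem <- bitwXor(rem, gf_mul(rep(coef, npar), gen[npar:1]))
    }
  }
  c(message, rem)
}

rs_syndromes <- function(received, params) {
  npar <- params$n - params$k_rs
  # r(x) = sum received[i] * x^(n-i), descending; S_j = r(alpha^(j+1))
  vapply(seq_len(npar), function(j) {
    a <- gf_pow(j)
    acc <- 0L
    for (s in received) acc <- bitwXor(gf_mul(acc, a), s)
    acc
  }, integer(1))
}

#' RS errors-and-erasures decoding
#'
#' Corrects f symbol errors and e erasures whenever 2f + e <= n - k_rs.
#'
#' @param received integer vector of `n` symbols (erased positions may hold
#'   any value, typically 0).
#' @param params an [rs_params].
#' @param erasures integer vector of 1-based erased positions (optional).
#' @return list with `message` (k_rs symbols or NULL), `ok` (logical),
#'   `corrected` (number of corrected symbol positions) and `status`.
#' @export
rs_decode <- function(received, params, erasures = integer(0)) {
  received <- as.integer(received)
  if (length(received) != params$n) stop("received word must have n = ", params$n, " symbols")
  erasures <- sort(unique(as.integer(erasures)))
  stopifnot(all(erasures >= 1 & erasures <= params$n))
  npar <- params$n - params$k_rs
  if (length(erasures) > npar) {
    return(list(message = NULL, ok = FALSE, corrected = 0L,
                status = "too many erasures"))
  }
  received[erasures] <- 0L
  S <- rs_syndromes(received, params)
  if (all(S == 0L) && length(erasures) == 0) {
    return(list(message = received[seq_len(params$k_rs)], ok = TRUE,
                corrected = 0L, status = "clean"))
  }
  n <- params$n
  e_cnt <- length(erasures)
  # erasure locator: product of (1 + X_e x), X_e = alpha^(n - pos)
  Xe <- gf_pow(n - erasures)
  gamma <- 1L
  for (xv in Xe) gamma <- poly_mul(gamma, c(1L, xv))
  # Berlekamp-Massey with erasure initialization
  lam <- gamma
  old <- gamma
  if (npar > e_cnt) {
    for (i in seq_len(npar - e_cnt)) {
      K <- e_cnt + i            # 1-based syndrome index S[K]
      delta <- S[K]
      if (length(lam) > 1) {
        for (j in 1:(length(lam) - 1)) {
          if (K - j >= 1) delta <- bitwXor(delta, gf_mul(lam[j + 1], S[K - j]))
        }
      }
      old <- c(0L, old)         # multiply by x
      if (delta != 0L) {
        if (length(old) > length(lam)) {
          new_lam <- poly_scale(old, delta)
          old <- poly_scale(lam, gf_inv(delta))
          lam <- new_lam
        }
        lam <- poly_add(lam, poly_scale(old, delta))
      }
    }
  }
  lam <- poly_trim(lam)
  nerr <- length(lam) - 1       # degree = total errata count
  if (nerr - e_cnt < 0 || 2 * (nerr - e_cnt) + e_cnt > npar) {
    return(list(message = NULL, ok = FALSE, corrected = 0L,
                status = "locator degree out of range"))
  }
  # Chien search over all positions
  pos <- integer(0)
  for (i in seq_len(n)) {
    Xi_inv <- gf_pow(-(n - i))
    if (poly_eval(lam, Xi_inv) == 0L) pos <- c(pos, i)
  }
  if (length(pos) != nerr) {
    return(list(message = NULL, ok = FALSE, corrected = 0L,
                status = "locator roots do not match degree"))
  }
  # Forney: Omega = S(x) * Lambda(x) mod x^npar ; fcr = 1
  Spoly <- as.integer(S)        # ascending: S_1 is coeff of x^0
  omega <- poly_mul(Spoly, lam)
  omega <- poly_trim(omega[seq_len(min(length(omega), npar))])
  lam_deriv <- lam[-1]          # formal derivative in char 2:
  if (length(lam_deriv) >= 2) { # keep odd-power terms only
    idx <- seq_along(lam_deriv)
    lam_deriv[idx %% 2 == 0] <- 0L
  }
  lam_deriv <- poly_trim(lam_deriv)
  corrected <- received
  for (i in pos) {
    Xi <- gf_pow(n - i)
    Xi_inv <- gf_inv(Xi)
    denom <- poly_eval(lam_deriv, Xi_inv)
    if (denom == 0L) {
      return(list(message = NULL, ok = FALSE, corrected = 0L,
                  status = "Forney denominator zero"))
    }
    mag <- gf_div(poly_eval(omega, Xi_inv), denom)
    corrected[i] <- bitwXor(corrected[i], mag)
  }
  if (any(rs_syndromes(corrected, params) != 0L)) {
    return(list(message = NULL, ok = FALSE, corrected = 0L,
                status = "residual syndromes after correction"))
  }
  list(message = corrected[seq_len(params$k_rs)], ok = TRUE,
       corrected = length(pos), status = "corrected")
}

#' Pack bits into 12-bit symbols / unpack symbols into bits
#'
#' Big-endian packing; the final partial symbol is zero-filled, and
#' `unpack_symbols` restores exactly `bit_len` bits.
#'
#' @param bits integer vector of 0/1.
#' @return integer vector of symbols in 0..4095.
#' @export
pack_bits <- function(bits) {
  bits <- as.integer(bits)
  stopifnot(all(bits %in% c(0L, 1L)))
  pad <- (GF_M - length(bits) %% GF_M) %% GF_M
  padded <- c(bits, integer(pad))
  m <- matrix(padded, nrow = GF_M)
  as.integer(colSums(m * 2^((GF_M - 1):0)))
}

#' @rdname pack_bits
#' @param symbols integer vector of 12-bit symbols.
#' @param bit_len original bit length to restore.
#' @export
unpack_symbols <- function(symbols, bit_len) {
  out <- integer(length(symbols) * GF_M)
  for (i in seq_len(GF_M)) {
    out[seq(i, by = GF_M, length.out = length(symbols))] <-
      (symbols %/% 2^(GF_M - i)) %% 2
  }
  as.integer(out[seq_len(bit_len)])
}
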