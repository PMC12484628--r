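#' k-mer current-level models
#'
#' A `kmer_model` maps every k-mer over {A,C,G,T} to the mean and standard
#' deviation (both in pA) of the nanopore current observed while that k-mer
#' occupies the pore, in the style of the ONT pore-model tables. The aggregate
#' noise scale `sigma_hat` -- the arithmetic mean of the per-k-mer standard
#' deviations -- drives the intersymbol-interference mitigation rule.
#'
#' @name kmer_model
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Enumerate all k-mers in lexicographic order
#'
#' @param k window length in bases.
#' @return character vector of length `4^k`.
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1)
  out <- DNA_BASES
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      out <- as.vector(t(outer(out, DNA_BASES, paste0)))
    }
  }
  sort(out)
}

new_kmer_model <- function(k, kmers, mean_pA, stdev_pA) {
  ord <- order(kmers)
  m <- structure(
    list(
      k = as.integer(k),
      kmers = kmers[ord],
      mean_pA = as.numeric(mean_pA)[ord],
      stdev_pA = as.numeric(stdev_pA)[ord],
      sigma_hat = mean(as.numeric(stdev_pA))
    ),
    class = "kmer_model"
  )
  names(m$mean_pA) <- m$kmers
  names(m$stdev_pA) <- m$kmers
  m
}

validate_kmer_model_rows <- function(kmers, mean_pA, stdev_pA, k) {
  bad <- !grepl(sprintf("^[ACGT]{%d}$", k), kmers)
  if (any(bad)) {
    stop("non-ACGT or wrong-length k-mer(s): ",
         paste(utils::head(kmers[bad], 5), collapse = ", "))
  }
  dup <- kmers[duplicated(kmers)]
  if (length(dup) > 0) {
    stop("duplicate k-mer(s): ", paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  expected <- all_kmers(k)
  missing <- setdiff(expected, kmers)
  if (length(missing) > 0) {
    stop("missing k-mer(s): ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else "")
  }
  if (any(!is.finite(mean_pA))) {
    stop("non-finite mean for k-mer(s): ",
         paste(utils::head(kmers[!is.finite(mean_pA)], 5), collapse = ", "))
  }
  if (any(!is.finite(stdev_pA) | stdev_pA <= 0)) {
    stop("non-positive or non-finite stdev for k-mer(s): ",
         paste(utils::head(kmers[!(is.finite(stdev_pA) & stdev_pA > 0)], 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Load a k-mer model table
#'
#' Reads a tab-separated pore-model table with columns `kmer`, `level_mean`,
#' `level_stdv` (header optional; a header line is detected by its first field
#' starting with "kmer"). Extra columns are ignored. The third column is
#' treated as a standard deviation in pA. `k` is inferred from the key length
#' and the table must be total: all `4^k` k-mers present exactly once.
#'
#' @param path path to the TSV file.
#' @return a `kmer_model`.
#' @export
load_kmer_model <- function(path) {
  if (!file.exists(path)) stop("model table not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^kmer", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3) stop("model table needs at least 3 columns (kmer, level_mean, level_stdv)")
  if (has_header) {
    cn <- tolower(colnames(tab))
    ik <- match("kmer", cn)
    im <- match("level_mean", cn)
    is <- match("level_stdv", cn)
    if (any(is.na(c(ik, im, is)))) { ik <- 1L; im <- 2L; is <- 3L }
  } else {
    ik <- 1L; im <- 2L; is <- 3L
  }
  kmers <- toupper(as.character(tab[[ik]]))
  mean_pA <- as.numeric(tab[[im]])
  stdev_pA <- as.numeric(tab[[is]])
  k <- nchar(kmers[1])
  validate_kmer_model_rows(kmers, mean_pA, stdev_pA, k)
  new_kmer_model(k, kmers, mean_pA, stdev_pA)
}

#' Generate a synthetic k-mer model
#'
#' Deterministic (seeded) stand-in for a real pore-model table: per-k-mer
#' means drawn uniformly in `[mean_low, mean_high]` pA and standard deviations
#' in `[stdev_low, stdev_high]` pA. The default ranges (60-120 pA means,
#' 1-3 pA stdevs) sit in the same range as published r9.4.1 tables, so
#' current-difference thresholds of a few pA are meaningful.
#'
#' @param k window length in bases.
#' @param seed integer seed; same seed, same table.
#' @param mean_low,mean_high range for the mean level (pA).
#' @param stdev_low,stdev_high range for the level standard deviation (pA).
#' @return a `kmer_model`.
#' @export
synthetic_kmer_model <- function(k = 6, seed = 1,
                                 mean_low = 60, mean_high = 120,
                                 stdev_low = 1, stdev_high = 3) {
  stopifnot(k >= 1)
  if (!(mean_low < mean_high)) stop("mean_low must be < mean_high")
  if (!(stdev_low > 0 && stdev_low <= stdev_high)) {
    stop("need 0 < stdev_low <= stdev_high")
  }
  kmers <- all_kmers(k)
  n <- length(kmers)
  vals <- withr::with_seed(as.integer(seed), {
    list(mu = stats::runif(n, mean_low, mean_high),
         sd = stats::runif(n, stdev_low, stdev_high))
  })
  new_kmer_model(k, kmers, vals$mu, vals$sd)
}

#' Write a k-mer model table
#'
#' Writes the ONT-style TSV (`kmer`, `level_mean`, `level_stdv`) with full
#' decimal precision so that `load_kmer_model(write_kmer_model(m))` is the
#' identity.
#'
#' @param model a `kmer_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kmer_model <- function(model, path) {
  stopifnot(inherits(model, "kmer_model"))
  lines <- c("kmer\tlevel_mean\tlevel_stdv",
             sprintf("%s\t%s\t%s", model$kmers,
                     format(model$mean_pA, digits = 17, trim = TRUE, scientific = FALSE),
                     format(model$stdev_pA, digits = 17, trim = TRUE, scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.kmer_model <- function(x, ...) {
  cat(sprintf("kmer_model: k=%d, %d k-mers, mean level %.2f-%.2f pA, sigma_hat=%.3f pA\n",
              x$k, length(x$kmers), min(x$mean_pA), max(x$mean_pA), x$sigma_hat))
  invisible(x)
}

#' @export
as.data.frame.kmer_model <- function(x, ...) {
  data.frame(kmer = x$kmers, level_mean = unname(x$mean_pA),
             level_stdv = unname(x$stdev_pA), stringsAsFactors = FALSE)
}
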