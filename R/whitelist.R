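# Barcode whitelists: construction, generation, file I/O.

#' Construct a barcode set
#'
#' A whitelist of legitimate barcode sequences for one split-pool round.
#' Sequences must be unique, equal-length ACGT strings; indices are the
#' 1-based positions in the set. The minimum pairwise Hamming distance is
#' computed exhaustively and stored as an attribute.
#'
#' @param sequences Character vector of DNA sequences.
#' @param round Optional round number (1..3).
#' @return A `data.frame` of class `sk_barcode_set` with columns `index` and
#'   `sequence`, attributes `min_pairwise_distance` and `round`.
#' @export
barcode_set <- function(sequences, round = NA_integer_) {
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("empty barcode set")
  if (!all(.is_dna(sequences)))
    stop("barcode sequences must be non-empty ACGT strings")
  if (length(unique(nchar(sequences))) != 1L)
    stop("barcode sequences must all have the same length")
  if (anyDuplicated(sequences))
    stop("duplicate barcode sequence: ",
         sequences[duplicated(sequences)][1L])
  out <- data.frame(index = seq_along(sequences), sequence = sequences,
                    stringsAsFactors = FALSE)
  attr(out, "min_pairwise_distance") <- .min_pairwise_distance(sequences)
  attr(out, "round") <- as.integer(round)
  class(out) <- c("sk_barcode_set", "data.frame")
  out
}

#' @exportS3Method base::print
print.sk_barcode_set <- function(x, ...) {
  cat("barcode set: ", nrow(x), " sequences of ", nchar(x$sequence[1L]),
      " nt, min pairwise Hamming distance ",
      attr(x, "min_pairwise_distance"), "\n", sep = "")
  invisible(x)
}

#' Generate a minimum-distance barcode whitelist
#'
#' Draws random barcodes and greedily accepts each candidate whose Hamming
#' distance to every previously accepted barcode is at least `min_distance`.
#' Deterministic for a fixed seed. The run aborts with a capacity error when
#' the request is infeasible outright (`n > 4^length`, or
#' `min_distance > length`) or when `max_rejects` consecutive candidates are
#' rejected, which indicates the random code is (close to) maximal.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in bases.
#' @param min_distance Required minimum pairwise Hamming distance.
#' @param seed Integer seed.
#' @param round Optional round annotation for the resulting set.
#' @param max_rejects Consecutive-rejection cap before giving up.
#' @return A [barcode_set()].
#' @export
generate_whitelist <- function(n, length, min_distance, seed = 1L,
                               round = NA_integer_, max_rejects = 50000L) {
  n <- as.integer(n); length <- as.integer(length)
  min_distance <- as.integer(min_distance)
  if (n < 1L) stop("n must be >= 1")
  if (min_distance > length)
    stop("capacity error: min_distance ", min_distance,
         " exceeds barcode length ", length)
  if (n > 4^length)
    stop("capacity error: ", n, " barcodes requested but only ",
         format(4^length, scientific = FALSE), " strings of length ",
         length, " exist")
  set.seed(seed)
  acc <- matrix(0L, n, length)
  k <- 0L; rejects <- 0L
  while (k < n) {
    cand <- sample.int(4L, length, replace = TRUE)
    ok <- TRUE
    if (k > 0L) {
      d <- .rowSums(acc[seq_len(k), , drop = FALSE] !=
                      rep(cand, each = k), k, length)
      ok <- min(d) >= min_distance
    }
    if (ok) {
      k <- k + 1L
      acc[k, ] <- cand
      rejects <- 0L
    } else {
      rejects <- rejects + 1L
      if (rejects >= max_rejects)
        stop("capacity error: gave up after ", max_rejects,
             " consecutive rejections with ", k, " of ", n,
             " barcodes accepted (length ", length, ", min distance ",
             min_distance, ")")
    }
  }
  barcode_set(.int2seq(acc), round = round)
}

#' Read a whitelist from a TSV file
#'
#' Expects one record per line, `index<TAB>sequence`, no header. Indices
#' must run 1..n contiguously; sequences must be unique equal-length ACGT
#' strings. Parse problems are reported with their line number.
#'
#' @param file Path to the TSV file.
#' @param round Optional round annotation.
#' @return A [barcode_set()].
#' @export
load_whitelist <- function(file, round = NA_integer_) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("whitelist file is empty: ", file)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  seqs <- character(length(lines))
  for (i in seq_along(lines)) {
    p <- parts[[i]]
    if (length(p) != 2L)
      stop("whitelist parse error at line ", i, ": expected 2 tab-separated ",
           "fields, got ", length(p))
    idx <- suppressWarnings(as.integer(p[1L]))
    if (is.na(idx) || idx != i)
      stop("whitelist parse error at line ", i, ": index '", p[1L],
           "' breaks the contiguous 1..n numbering")
    if (!.is_dna(p[2L]))
      stop("whitelist parse error at line ", i,
           ": sequence contains non-ACGT characters")
    seqs[i] <- p[2L]
  }
  if (length(unique(nchar(seqs))) != 1L) {
    bad <- which(nchar(seqs) != nchar(seqs[1L]))[1L]
    stop("whitelist parse error at line ", bad, ": ragged sequence length")
  }
  if (anyDuplicated(seqs)) {
    bad <- which(duplicated(seqs))[1L]
    stop("whitelist parse error at line ", bad, ": duplicate sequence ",
         seqs[bad])
  }
  barcode_set(seqs, round = round)
}

#' Write a whitelist to a TSV file
#'
#' @param set A [barcode_set()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_whitelist <- function(set, file) {
  stopifnot(inherits(set, "sk_barcode_set"))
  writeLines(paste(set$index, set$sequence, sep = "\t"), file)
  invisible(file)
}
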