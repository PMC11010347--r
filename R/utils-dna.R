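# Low-level DNA sequence utilities shared across modules: integer encodings,
# batch Hamming distance, minimum-distance code generation.

.BASES <- c("A", "C", "G", "T")

# lookup from UTF-8 code point to base code 1..4; anything else NA
.BASE_LOOKUP <- local({
  v <- rep(NA_integer_, 128L)
  v[utf8ToInt("A")] <- 1L
  v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L
  v[utf8ToInt("T")] <- 4L
  v
})

# Character vector of equal-length DNA strings -> integer matrix (n x len),
# base codes 1..4, NA for non-ACGT.
.seq2int <- function(x, len = NULL) {
  n <- length(x)
  if (n == 0L) return(matrix(integer(0), 0L, if (is.null(len)) 0L else len))
  nc <- nchar(x)
  if (is.null(len)) len <- nc[1L]
  if (any(nc != len)) stop("sequences are not all of length ", len)
  if (len == 0L) return(matrix(integer(0), n, 0L))
  codes <- utf8ToInt(paste0(x, collapse = ""))
  codes[codes > 127L] <- utf8ToInt("N")
  m <- matrix(.BASE_LOOKUP[codes], nrow = len, ncol = n)
  t(m)
}

# Integer matrix (n x len, codes 1..4) -> character vector of DNA strings.
.int2seq <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  if (ncol(m) == 0L) return(rep("", nrow(m)))
  ch <- matrix(.BASES[m], nrow = nrow(m), ncol = ncol(m))
  do.call(paste0, as.data.frame(ch, stringsAsFactors = FALSE))
}

.is_dna <- function(x) {
  !is.na(x) & grepl("^[ACGT]+$", x)
}

#' Hamming distance between equal-length sequences
#'
#' Number of mismatching positions between `a` and `b`. Vectorised
#' elementwise over pairs (the usual recycling rules apply).
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming("AAAA", "AAAT")
#' @export
hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (any(nchar(a) != nchar(b)))
    stop("hamming() requires equal-length strings")
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- sum(utf8ToInt(a[i]) != utf8ToInt(b[i]))
  }
  out
}

#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (substitutions, insertions, deletions),
#' computed with [utils::adist()]. Vectorised elementwise over pairs.
#'
#' @param a,b Character vectors.
#' @return Integer vector of edit distances.
#' @examples
#' levenshtein("kitten", "sitting")
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(utils::adist(a[i], b[i]))
  out
}

# Full n x m Hamming distance matrix between two integer-encoded sets
# (rows are sequences). Used for whitelist correction and audits.
.hamming_cross <- function(a_int, b_int) {
  n <- nrow(a_int); m <- nrow(b_int); len <- ncol(a_int)
  stopifnot(len == ncol(b_int))
  D <- matrix(0L, n, m)
  for (l in seq_len(len)) {
    D <- D + outer(a_int[, l], b_int[, l], "!=")
  }
  storage.mode(D) <- "integer"
  D
}

# Minimum pairwise Hamming distance within a set of sequences (exhaustive).
.min_pairwise_distance <- function(seqs) {
  if (length(seqs) < 2L) return(NA_integer_)
  m <- .seq2int(seqs)
  D <- .hamming_cross(m, m)
  diag(D) <- NA_integer_
  min(D, na.rm = TRUE)
}

# Draw, for each of n rows, s positions out of len without replacement.
# Returns n x s integer matrix. Vectorised via iterated argmax on a random
# key matrix (no per-row sampling loop).
.sample_positions <- function(n, len, s) {
  if (n == 0L) return(matrix(integer(0), 0L, s))
  key <- matrix(stats::runif(n * len), n, len)
  pos <- matrix(0L, n, s)
  for (j in seq_len(s)) {
    p <- max.col(key, ties.method = "first")
    pos[, j] <- p
    key[cbind(seq_len(n), p)] <- -1
  }
  pos
}

# --- GF(4) arithmetic and shortened quaternary Hamming codes ---------------
# Elements 0..3 encode {0, 1, w, w^2} with w^2 = w + 1; addition is XOR of
# the 2-bit representation; multiplication by lookup table.

.GF4_MULT <- matrix(c(
  0L, 0L, 0L, 0L,
  0L, 1L, 2L, 3L,
  0L, 2L, 3L, 1L,
  0L, 3L, 1L, 2L), 4L, 4L, byrow = TRUE)

.gf4_add <- function(a, b) bitwXor(a, b)
.gf4_mul <- function(a, b) .GF4_MULT[cbind(a + 1L, b + 1L)]

# Normalised projective points of PG(r-1, 4) as columns of an r x N matrix,
# in a fixed deterministic order, excluding the standard basis vectors.
.pg4_points <- function(r) {
  grid <- as.matrix(expand.grid(rep(list(0L:3L), r)))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  # normalise: first nonzero coordinate (scanning from the left) equals 1
  first_nz <- apply(grid, 1L, function(v) v[which(v != 0L)[1L]])
  keep <- first_nz == 1L
  pts <- grid[keep, , drop = FALSE]
  # a normalised point is a standard basis vector iff its only nonzero
  # coordinate is the leading 1
  is_basis <- rowSums(pts != 0L) == 1L
  t(pts[!is_basis, , drop = FALSE])
}

# All codewords of a shortened quaternary Hamming code of the given length
# and minimum distance 3, as an integer matrix (4^(length-r) rows) over
# codes 0..3. r is the smallest redundancy with (4^r - 1)/3 >= length.
# Optionally only `n` codewords are materialised, chosen by seeded sampling
# of message vectors without replacement.
.hamming4_code <- function(length, n = NULL) {
  r <- 2L
  while ((4^r - 1) / 3 < length) r <- r + 1L
  k <- length - r
  if (k < 1L)
    stop("no distance-3 code of length ", length, " with this construction")
  capacity <- 4^k
  if (is.null(n)) n <- capacity
  if (n > capacity)
    stop("requested ", n, " codewords but the distance-3 code of length ",
         length, " holds at most ", format(capacity, scientific = FALSE))
  # parity-check H = [A | I_r]; columns of A are distinct non-basis
  # projective points, so all columns of H are pairwise linearly independent
  A <- .pg4_points(r)[, seq_len(k), drop = FALSE]
  msg_id <- if (n == capacity) seq_len(capacity) - 1 else
    sample(capacity, n) - 1
  # message digits base 4, least significant first
  M <- matrix(0L, n, k)
  rem <- msg_id
  for (j in seq_len(k)) {
    M[, j] <- as.integer(rem %% 4)
    rem <- rem %/% 4
  }
  P <- matrix(0L, n, r)
  for (j in seq_len(r)) {
    acc <- rep(0L, n)
    for (i in seq_len(k)) acc <- .gf4_add(acc, .gf4_mul(A[j, i], M[, i]))
    P[, j] <- acc
  }
  cbind(M, P)
}
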