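# Quantification: random-hexamer collapsing, feature assignment, UMI
# deduplication into a sparse cell x feature matrix, and the read-support
# cell filter.

#' Sparse UMI count matrix container
#'
#' Wraps a sparse cells-by-features UMI count matrix (`Matrix::dgCMatrix`,
#' row names are `bc1-bc2-bc3` index triplets) together with the per-cell
#' assigned-read totals used by the cell filter.
#'
#' @param counts Sparse or dense matrix, cells in rows (named by barcode
#'   triplet token), features in columns.
#' @param reads Named integer vector of per-cell read totals; names must
#'   match the matrix row names.
#' @return An object of class `sk_counts`.
#' @export
sk_counts <- function(counts, reads) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) == 0L && is.null(rownames(counts)))
    dimnames(counts) <- list(character(0), colnames(counts))
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique cell (row) names")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  reads <- reads[rownames(counts)]
  if (any(is.na(reads)))
    stop("per-cell read totals missing for some cells")
  reads <- stats::setNames(as.integer(reads), rownames(counts))
  structure(list(counts = counts, reads = reads), class = "sk_counts")
}

#' @exportS3Method base::print
print.sk_counts <- function(x, ...) {
  cat("UMI count matrix: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " features, ", sum(x$counts), " UMIs, ",
      format(sum(x$reads), scientific = FALSE), " assigned reads\n",
      sep = "")
  invisible(x)
}

#' @export
dim.sk_counts <- function(x) dim(x$counts)

.cell_tokens <- function(bc1, bc2, bc3) paste(bc1, bc2, bc3, sep = "-")

#' Collapse a random-hexamer round-1 barcode index
#'
#' In hexamer mode the round-1 plate pairs each oligo-dT barcode (indices
#' `1..hexamer_split`) with a random-hexamer barcode in the same well
#' (indices `hexamer_split+1..2*hexamer_split`): index 49 collapses to 1,
#' 96 to 48, while 48 stays 48. Collapsing subtracts `hexamer_split` from
#' every index larger than `hexamer_split`.
#'
#' @param bc1_index Integer vector of round-1 barcode indices.
#' @param hexamer_split Number of oligo-dT barcodes (default 48).
#' @param n_round1 Size of the round-1 whitelist (default 96); indices
#'   outside `1..n_round1` are an error.
#' @return Integer vector of collapsed indices.
#' @examples
#' collapse_hexamer_index(c(1, 48, 49, 96))
#' @export
collapse_hexamer_index <- function(bc1_index, hexamer_split = 48L,
                                   n_round1 = 96L) {
  bc1_index <- as.integer(bc1_index)
  if (any(is.na(bc1_index) | bc1_index < 1L | bc1_index > n_round1))
    stop("round-1 barcode index out of range 1..", n_round1)
  ifelse(bc1_index > hexamer_split, bc1_index - as.integer(hexamer_split),
         bc1_index)
}

#' Collapse random-hexamer cells in a count matrix
#'
#' Merges cells whose barcode triplets become identical after collapsing
#' the round-1 index (element-wise summation of counts and of read
#' totals). Total counts are conserved exactly and the operation is
#' idempotent.
#'
#' @param x An [sk_counts()] object with pre-collapse round-1 indices.
#' @param hexamer_split Number of oligo-dT barcodes (default 48).
#' @param n_round1 Size of the round-1 whitelist (default 96).
#' @return A collapsed [sk_counts()] object.
#' @export
collapse_matrix <- function(x, hexamer_split = 48L, n_round1 = 96L) {
  stopifnot(inherits(x, "sk_counts"))
  if (nrow(x$counts) == 0L) return(x)
  parts <- data.table::tstrsplit(rownames(x$counts), "-", fixed = TRUE,
                                 type.convert = TRUE)
  new_bc1 <- collapse_hexamer_index(parts[[1L]], hexamer_split, n_round1)
  token <- .cell_tokens(new_bc1, parts[[2L]], parts[[3L]])
  grp <- factor(token, levels = unique(token))
  G <- Matrix::sparseMatrix(i = as.integer(grp),
                            j = seq_along(token), x = 1,
                            dims = c(nlevels(grp), length(token)),
                            dimnames = list(levels(grp), NULL))
  merged <- G %*% x$counts
  # rowsum over integer group ids returns rows sorted 1..k = level order
  reads <- as.integer(rowsum(as.numeric(x$reads), as.integer(grp))[, 1L])
  names(reads) <- levels(grp)
  sk_counts(merged, reads)
}

#' Assign a cDNA read to a feature reference
#'
#' Compares each read against every reference by positional identity
#' (matching bases over the reference length) and returns the best
#' reference when its identity reaches `min_identity` and is unique;
#' otherwise `NA` (unassigned). References must be equal length and
#' pairwise distinguishable.
#'
#' @param reads Character vector of cDNA (read 1) sequences.
#' @param references Named character vector of reference sequences.
#' @param min_identity Minimum fraction of matching positions (default
#'   0.9).
#' @return Character vector of feature ids (`NA` where unassigned).
#' @export
assign_feature <- function(reads, references, min_identity = 0.9) {
  if (is.null(names(references)))
    stop("references must be named")
  rlen <- unique(nchar(references))
  if (length(rlen) != 1L)
    stop("references must have equal length")
  n <- length(reads)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  ref_int <- .seq2int(references, rlen)
  cmp_len <- pmin(nchar(reads), rlen)
  for (L in unique(cmp_len)) {
    w <- which(cmp_len == L)
    if (L == 0L) next
    m <- .seq2int(substring(reads[w], 1L, L), L)
    m[is.na(m)] <- 0L
    D <- .hamming_cross(m, ref_int[, seq_len(L), drop = FALSE])
    ident <- (L - D + 0) / rlen      # unread tail counts as mismatch
    best <- do.call(pmax, as.data.frame(ident))
    argbest <- max.col(ident, ties.method = "first")
    ties <- .rowSums(ident == best, nrow(ident), ncol(ident)) > 1L
    ok <- best >= min_identity & !ties
    out[w[ok]] <- names(references)[argbest[ok]]
  }
  out
}

#' Build the UMI count matrix from assigned reads
#'
#' Counts, for every (cell, feature) pair, the number of distinct UMIs
#' among the contributing reads (exact-match deduplication: the simulator's
#' within-cell UMI code keeps distinct molecules at Hamming distance >= 3,
#' so near-match merging is unnecessary). Per-cell read totals count every
#' contributing read, before deduplication.
#'
#' @param assignments A data.frame/data.table of reads with columns `bc1`,
#'   `bc2`, `bc3` (corrected indices), `umi` and `feature_id`; typically
#'   the `assigned` rows of a [demux()] table joined with
#'   [assign_feature()] output.
#' @param features Optional character vector fixing the feature universe
#'   and column order (default: sorted unique observed features).
#' @return An [sk_counts()] object.
#' @export
build_count_matrix <- function(assignments, features = NULL) {
  dt <- data.table::as.data.table(assignments)
  need <- c("bc1", "bc2", "bc3", "umi", "feature_id")
  if (!all(need %in% names(dt)))
    stop("assignments must have columns ", paste(need, collapse = ", "))
  dt <- dt[!is.na(bc1) & !is.na(bc2) & !is.na(bc3) & !is.na(feature_id)]
  dt[, cell := .cell_tokens(bc1, bc2, bc3)]
  if (is.null(features)) features <- sort(unique(dt$feature_id))
  reads_per_cell <- dt[, .N, by = cell]
  dedup <- unique(dt[, .(cell, feature_id, umi)])
  tab <- dedup[, .N, by = .(cell, feature_id)]
  cell_levels <- reads_per_cell$cell
  counts <- Matrix::sparseMatrix(
    i = match(tab$cell, cell_levels),
    j = match(tab$feature_id, features),
    x = tab$N,
    dims = c(length(cell_levels), length(features)),
    dimnames = list(cell_levels, features))
  reads <- reads_per_cell$N
  names(reads) <- cell_levels
  sk_counts(counts, reads)
}

#' Filter cells by assigned-read support
#'
#' Retains cells with strictly more than `min_reads` reads assigned to
#' them (default 100).
#'
#' @param x An [sk_counts()] object.
#' @param min_reads Read threshold; cells with totals `> min_reads` are
#'   kept.
#' @return A filtered [sk_counts()] object.
#' @export
filter_cells <- function(x, min_reads = 100L) {
  stopifnot(inherits(x, "sk_counts"))
  keep <- x$reads > min_reads
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out$reads <- x$reads[keep]
  out
}

#' Write a count matrix as MatrixMarket triplets
#'
#' Writes `matrix.mtx` (features x cells orientation is *not* used; the
#' matrix is written cells-in-rows exactly as stored), `barcodes.tsv`
#' (`bc1-bc2-bc3` tokens) and `features.tsv` into `dir`, mirroring the
#' conventional triplet layout.
#'
#' @param x An [sk_counts()] object.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "sk_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "features.tsv"))
  writeLines(paste(rownames(x$counts), x$reads, sep = "\t"),
             file.path(dir, "read_totals.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` and `read_totals.tsv`.
#' @return An [sk_counts()] object.
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  colnames(m) <- readLines(file.path(dir, "features.tsv"))
  rt <- utils::read.table(file.path(dir, "read_totals.tsv"), sep = "\t",
                          col.names = c("cell", "reads"),
                          colClasses = c("character", "integer"))
  reads <- rt$reads
  names(reads) <- rt$cell
  sk_counts(m, reads)
}
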