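# Streaming summary of simulator truth from read names, for auditing
# datasets too large to hold in memory.

#' Summarise simulator truth by streaming read names
#'
#' Streams a simulator FASTQ (read 1 or read 2; plain or gzipped), parses
#' the truth fields from every read name and accumulates the distinct true
#' cell-barcode triplets, per-cell read counts and per-category read
#' counts without loading the file into memory.
#'
#' @param path FASTQ path.
#' @param chunk_reads Reads per streaming chunk (default 1e6).
#' @return List with `n_reads`, `cell_barcodes` (distinct `bc1-bc2-bc3`
#'   truth tokens), `reads_per_cell` (named integer, by `cell_id`) and
#'   `category_counts` (named integer over [SK_CATEGORIES]).
#' @export
summarize_truth_names <- function(path, chunk_reads = 1000000L) {
  con <- file(path, open = "r")
  on.exit(close(con), add = TRUE)
  tokens <- character(0)
  per_cell <- integer(0)
  cat_counts <- integer(length(SK_CATEGORIES))
  names(cat_counts) <- SK_CATEGORIES
  n_reads <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_reads, warn = FALSE)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ file ", path)
    heads <- lines[seq(1L, length(lines), by = 4L)]
    truth <- parse_read_name(sub("\\s.*$", "", substring(heads, 2L)))
    n_reads <- n_reads + nrow(truth)
    tokens <- unique(c(tokens,
                       unique(.cell_tokens(truth$bc1, truth$bc2,
                                           truth$bc3))))
    cc <- truth[, .N, by = cell_id]
    idx <- as.character(cc$cell_id)
    old <- per_cell[idx]
    old[is.na(old)] <- 0L
    per_cell[idx] <- old + cc$N
    tab <- table(factor(truth$category, levels = SK_CATEGORIES))
    cat_counts <- cat_counts + as.integer(tab)
  }
  list(n_reads = n_reads, cell_barcodes = tokens,
       reads_per_cell = per_cell, category_counts = cat_counts)
}
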