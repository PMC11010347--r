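# Benchmarking demultiplexer output against simulated ground truth:
# per-category capture rates, barcode recovery, strategy overlap and
# per-cell summary statistics.

.CORRECTABLE_SET <- c("perfect", "correctable_1", "correctable_2",
                      "correctable_3")
.UNCORRECTABLE_SET <- c("uncorrectable_1", "uncorrectable_2",
                        "uncorrectable_3")

#' Join demultiplexer calls with simulation truth
#'
#' Produces one evaluation record per read with the truth cell triplet,
#' the called triplet (or none) and an outcome: `correct` when the called
#' triplet equals the truth, `miscorrected` when a triplet was called but
#' differs, `dropped` when no triplet was assigned. Captured reads are
#' defined as `correct` only; miscorrections are reported separately (their
#' sum with `correct` recovers a looser captured-if-assigned reading).
#'
#' @param calls A [correct_call()]/[demux()] table.
#' @param truth Truth table with columns `read_id`, `category`, `bc1`,
#'   `bc2`, `bc3` (e.g. from [parse_read_name()] or `truth.tsv`). Every
#'   call's `read_id` must appear in it.
#' @return `data.table` with columns `read_id`, `category`, `truth_cell`,
#'   `called_cell`, `outcome`.
#' @export
join_truth <- function(calls, truth) {
  calls <- data.table::as.data.table(calls)
  truth <- data.table::as.data.table(truth)
  missing <- setdiff(calls$read_id, truth$read_id)
  if (length(missing) > 0L)
    stop("read ids absent from truth: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "")
  tr <- truth[, .(read_id, category,
                  truth_cell = .cell_tokens(bc1, bc2, bc3))]
  ev <- merge(calls[, .(read_id, bc1_idx, bc2_idx, bc3_idx, status)],
              tr, by = "read_id", sort = FALSE)
  ev[, called_cell := ifelse(status == "assigned",
                             .cell_tokens(bc1_idx, bc2_idx, bc3_idx),
                             NA_character_)]
  ev[, outcome := data.table::fifelse(
    is.na(called_cell), "dropped",
    data.table::fifelse(called_cell == truth_cell, "correct",
                        "miscorrected"))]
  ev[, .(read_id, category, truth_cell, called_cell, outcome)]
}

#' Capture rates by category or correctability group
#'
#' The capture rate of a group is the fraction of its reads whose corrected
#' cell barcode equals the simulated truth. With `grouping = "group"` the
#' categories are aggregated into the correctable group (perfect plus the
#' three correctable categories), the uncorrectable group, and `random`
#' reported separately.
#'
#' @param records Evaluation records from [join_truth()].
#' @param grouping `"category"` or `"group"`.
#' @return `data.table` with columns `group`, `n`, `captured`,
#'   `miscorrected`, `capture_rate`, `miscorrection_rate`.
#' @export
capture_rates <- function(records, grouping = c("category", "group")) {
  grouping <- match.arg(grouping)
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) stop("no evaluation records")
  if (grouping == "category") {
    records[, group := factor(category, levels = SK_CATEGORIES)]
  } else {
    records[, group := data.table::fcase(
      category %in% .CORRECTABLE_SET, "correctable",
      category %in% .UNCORRECTABLE_SET, "uncorrectable",
      default = "random")]
    records[, group := factor(group, levels = c("correctable",
                                                "uncorrectable", "random"))]
  }
  out <- records[, .(n = .N,
                     captured = sum(outcome == "correct"),
                     miscorrected = sum(outcome == "miscorrected")),
                 by = group][order(group)]
  out[, capture_rate := captured / n]
  out[, miscorrection_rate := miscorrected / n]
  out[]
}

#' Barcode recovery against the truth cell set
#'
#' Set comparison of the (post-filter) matrix cell triplets with the true
#' cell triplets: `found` truth cells present in the matrix, `missed`
#' truth cells absent, `spurious` matrix cells that match no truth cell.
#'
#' @param x An [sk_counts()] object or a character vector of cell triplet
#'   tokens.
#' @param truth_cells Character vector of true cell triplet tokens (on the
#'   same collapse level as `x`).
#' @return Named integer vector `c(found, missed, spurious)`.
#' @export
barcode_recovery <- function(x, truth_cells) {
  cells <- if (inherits(x, "sk_counts")) rownames(x$counts) else
    as.character(x)
  truth_cells <- unique(as.character(truth_cells))
  c(found = length(intersect(truth_cells, cells)),
    missed = length(setdiff(truth_cells, cells)),
    spurious = length(setdiff(cells, truth_cells)))
}

#' Exclusive strategy-overlap (upset) counts
#'
#' For named sets of cell barcodes, counts every non-empty subset of set
#' names by exclusive membership: each barcode contributes to exactly one
#' row, the row of the full combination of sets containing it, so the rows
#' sum to the size of the union.
#'
#' @param cb_sets Named list (length >= 2) of character vectors.
#' @return `data.table` with one logical column per set, the `degree`, and
#'   the exclusive `count`, ordered by decreasing degree then count.
#' @export
strategy_overlap <- function(cb_sets) {
  if (length(cb_sets) < 2L || is.null(names(cb_sets)))
    stop("cb_sets must be a named list of at least 2 sets")
  universe <- unique(unlist(cb_sets, use.names = FALSE))
  members <- vapply(cb_sets, function(s) universe %in% s,
                    logical(length(universe)))
  if (length(universe) == 1L) members <- matrix(members, nrow = 1L,
                                                dimnames = list(NULL,
                                                                names(cb_sets)))
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)),
                                      length(cb_sets))))
  colnames(combos) <- names(cb_sets)
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  pattern <- apply(members, 1L, paste0, collapse = "")
  key <- apply(combos, 1L, paste0, collapse = "")
  count <- as.integer(table(factor(pattern, levels = key)))
  out <- data.table::as.data.table(combos)
  out[, degree := rowSums(combos)]
  out[, count := count]
  out[order(-degree, -count)]
}

#' Per-cell summary statistics of a count matrix
#'
#' Genes per cell are the nonzero features of each cell; UMIs per cell are
#' the count sums. Means and medians are reported (the median over an even
#' number of cells is the midpoint mean).
#'
#' @param x An [sk_counts()] object.
#' @return List with `n_cells`, `mean_genes`, `median_genes`, `mean_umis`,
#'   `median_umis` (statistics `NA` when the matrix is empty).
#' @export
cell_stats <- function(x) {
  stopifnot(inherits(x, "sk_counts"))
  n <- nrow(x$counts)
  if (n == 0L)
    return(list(n_cells = 0L, mean_genes = NA_real_, median_genes = NA_real_,
                mean_umis = NA_real_, median_umis = NA_real_))
  genes <- Matrix::rowSums(x$counts > 0)
  umis <- Matrix::rowSums(x$counts)
  list(n_cells = n,
       mean_genes = mean(genes), median_genes = stats::median(genes),
       mean_umis = mean(umis), median_umis = stats::median(umis))
}

#' Assemble a benchmark report
#'
#' Combines per-category and per-group capture rates, barcode recovery,
#' per-cell statistics and (optionally) strategy overlap into one
#' machine-readable structure.
#'
#' @param records Evaluation records from [join_truth()].
#' @param matrix An [sk_counts()] object (post-filter), or `NULL`.
#' @param truth_cells True cell triplet tokens for recovery (same collapse
#'   level as `matrix`), or `NULL`.
#' @param cb_sets Optional named list of cell-barcode sets for
#'   [strategy_overlap()].
#' @return List of class `sk_benchmark_report`.
#' @export
benchmark_report <- function(records, matrix = NULL, truth_cells = NULL,
                             cb_sets = NULL) {
  rep <- list(
    capture_by_category = capture_rates(records, "category"),
    capture_by_group = capture_rates(records, "group"))
  if (!is.null(matrix) && !is.null(truth_cells)) {
    rep$recovery <- barcode_recovery(matrix, truth_cells)
    rep$cell_stats <- cell_stats(matrix)
  }
  if (!is.null(cb_sets) && length(cb_sets) >= 2L)
    rep$overlap <- strategy_overlap(cb_sets)
  class(rep) <- "sk_benchmark_report"
  rep
}

#' Write a benchmark report as JSON and TSV
#'
#' @param report An [benchmark_report()] object.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- list(
    capture_by_category = report$capture_by_category,
    capture_by_group = report$capture_by_group)
  if (!is.null(report$recovery)) ser$recovery <- as.list(report$recovery)
  if (!is.null(report$cell_stats)) ser$cell_stats <- report$cell_stats
  if (!is.null(report$overlap)) ser$overlap <- report$overlap
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(report$capture_by_category,
                     file.path(dir, "capture_rates.tsv"), sep = "\t")
  if (!is.null(report$overlap))
    data.table::fwrite(report$overlap, file.path(dir, "overlap.tsv"),
                       sep = "\t")
  invisible(dir)
}
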