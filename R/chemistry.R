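# Chemistry definitions: barcode-read geometry for the v1/v2 SPLiT-seq
# linker chemistries, default linker sequences, whitelist presets and
# combinatorial-space arithmetic.

# Fixed default linker sequences. The two protocol versions differ only in
# the length of linker 1 (22 nt in v2, 30 nt in v1); linker 2 is 30 nt in
# both. The sequences themselves are package defaults and can be overridden
# per chemistry; only their lengths are structurally constrained.
.DEFAULT_LINKERS <- list(
  v1 = list(linker1 = "GTGGCCGATGTTTCGCATCGGCGTACGACT",
            linker2 = "ATCCACGTGCTTGAGAGGCCAGAGCATTCG"),
  v2 = list(linker1 = "ATCCACGTGCTTGAGACTGTGG",
            linker2 = "ATCCACGTGCTTGAGAGGCCAGAGCATTCG")
)

.CHEM_LINKER_LEN <- list(
  v1 = c(linker1 = 30L, linker2 = 30L),
  v2 = c(linker1 = 22L, linker2 = 30L)
)

#' Define a SPLiT-seq chemistry
#'
#' Bundles the geometry parameters of the barcode read (UMI and barcode
#' lengths, linker sequences for the chosen protocol version), one barcode
#' whitelist per split-pool round, and the random-hexamer split of the
#' round-1 plate.
#'
#' In hexamer mode (`hexamer_split > 0`) the round-1 plate holds
#' `hexamer_split` oligo-dT barcodes (indices `1..hexamer_split`) and the
#' same number of random-hexamer barcodes (indices
#' `hexamer_split+1 .. 2*hexamer_split`) occupying the same physical wells,
#' so the round-1 whitelist must contain at least `2 * hexamer_split`
#' entries.
#'
#' @param version `"v1"` or `"v2"`. The versions differ in the length of
#'   linker 1 (30 nt vs 22 nt), which shifts the round-1 barcode on the read.
#' @param umi_length UMI length in bases (default 10).
#' @param bc_length Barcode length in bases (default 8).
#' @param linker1,linker2 Linker sequences (ACGT). Defaults are the package's
#'   fixed sequences of the version's canonical lengths.
#' @param whitelists List of three [barcode_set()] objects (rounds 1..3).
#'   Default: the `"realistic"` preset (96 barcodes per round, minimum
#'   pairwise Hamming distance 3).
#' @param hexamer_split Number of round-1 barcodes assigned to oligo-dT
#'   primers; the paired random-hexamer barcodes follow them on the plate.
#'   0 disables hexamer mode. Default 48.
#' @return An object of class `sk_chemistry`.
#' @seealso [build_layout()], [whitelist_preset()]
#' @export
chemistry <- function(version = c("v2", "v1"),
                      umi_length = 10L,
                      bc_length = 8L,
                      linker1 = NULL,
                      linker2 = NULL,
                      whitelists = NULL,
                      hexamer_split = 48L) {
  version <- match.arg(version)
  umi_length <- as.integer(umi_length)
  bc_length <- as.integer(bc_length)
  hexamer_split <- as.integer(hexamer_split)
  if (umi_length <= 0L || bc_length <= 0L)
    stop("umi_length and bc_length must be positive")
  if (hexamer_split < 0L) stop("hexamer_split must be >= 0")
  if (is.null(linker1)) linker1 <- .DEFAULT_LINKERS[[version]]$linker1
  if (is.null(linker2)) linker2 <- .DEFAULT_LINKERS[[version]]$linker2
  for (nm in c("linker1", "linker2")) {
    lk <- get(nm)
    if (length(lk) != 1L || !.is_dna(lk))
      stop(nm, " must be a single ACGT string")
    want <- .CHEM_LINKER_LEN[[version]][[nm]]
    if (nchar(lk) != want)
      stop("configuration error: ", nm, " has length ", nchar(lk),
           " but chemistry ", version, " requires ", want)
  }
  if (is.null(whitelists)) {
    whitelists <- whitelist_preset("realistic", bc_length = bc_length)
    if (hexamer_split == 48L && nrow(whitelists[[1L]]) < 2L * 48L)
      hexamer_split <- nrow(whitelists[[1L]]) %/% 2L
  }
  if (!is.list(whitelists) || length(whitelists) != 3L)
    stop("whitelists must be a list of 3 barcode sets (rounds 1..3)")
  for (r in 1:3) {
    wl <- whitelists[[r]]
    if (!inherits(wl, "sk_barcode_set"))
      stop("whitelists[[", r, "]] is not a barcode set")
    if (any(nchar(wl$sequence) != bc_length))
      stop("whitelists[[", r, "]] sequences do not have bc_length = ",
           bc_length)
  }
  if (hexamer_split > 0L && nrow(whitelists[[1L]]) < 2L * hexamer_split)
    stop("round-1 whitelist has ", nrow(whitelists[[1L]]),
         " entries but hexamer mode requires at least ", 2L * hexamer_split)
  structure(
    list(version = version,
         umi_length = umi_length,
         bc_length = bc_length,
         linker1 = linker1,
         linker2 = linker2,
         whitelists = whitelists,
         hexamer_split = hexamer_split),
    class = "sk_chemistry")
}

#' @exportS3Method base::print
print.sk_chemistry <- function(x, ...) {
  cat("SPLiT-seq chemistry ", x$version,
      ": UMI ", x$umi_length, " nt, barcodes ", x$bc_length,
      " nt, linkers ", nchar(x$linker1), "/", nchar(x$linker2), " nt\n",
      "whitelists: ", paste(vapply(x$whitelists, nrow, 0L), collapse = "/"),
      " barcodes (rounds 1/2/3); hexamer split ", x$hexamer_split, "\n",
      sep = "")
  invisible(x)
}

#' Derive the barcode-read layout of a chemistry
#'
#' Computes the coordinate map of the six elements on the barcode read, in
#' order UMI, BC3, LINKER2, BC2, LINKER1, BC1. All spans are 0-based
#' half-open intervals; with the default v2 parameters the barcode spans are
#' BC3 `[10,18)`, BC2 `[48,56)` and BC1 `[78,86)` (BC1 `[86,94)` for v1),
#' matching the positional configuration used by fixed-position extractors.
#'
#' @param chem An [chemistry()] object.
#' @return An object of class `sk_read_layout`: a list with `spans` (named
#'   list of `c(start, end)` 0-based half-open intervals) and `total_length`.
#' @export
build_layout <- function(chem) {
  stopifnot(inherits(chem, "sk_chemistry"))
  lens <- c(umi = chem$umi_length,
            bc3 = chem$bc_length,
            linker2 = nchar(chem$linker2),
            bc2 = chem$bc_length,
            linker1 = nchar(chem$linker1),
            bc1 = chem$bc_length)
  ends <- cumsum(lens)
  starts <- ends - lens
  spans <- mapply(function(s, e) c(s, e), starts, ends, SIMPLIFY = FALSE)
  structure(list(spans = spans, total_length = unname(ends[["bc1"]])),
            class = "sk_read_layout")
}

#' @exportS3Method base::print
print.sk_read_layout <- function(x, ...) {
  cat("barcode-read layout, total", x$total_length, "nt\n")
  for (nm in names(x$spans))
    cat(sprintf("  %-8s [%d,%d)\n", nm, x$spans[[nm]][1], x$spans[[nm]][2]))
  invisible(x)
}

# 1-based substring bounds of a layout span
.span_bounds <- function(layout, element) {
  sp <- layout$spans[[element]]
  c(sp[1] + 1L, sp[2])
}

#' Size of the combinatorial cell-barcode space
#'
#' The number of distinct cell barcodes available from a split-pool design,
#' `barcodes_per_round ^ rounds`: with 96 barcodes and 3 rounds, 884,736
#' combinations.
#'
#' @param barcodes_per_round Barcodes available in each round.
#' @param rounds Number of split-pool rounds.
#' @return Numeric count.
#' @examples
#' max_unique_barcodes(96, 3)
#' @export
max_unique_barcodes <- function(barcodes_per_round, rounds) {
  if (barcodes_per_round < 1 || rounds < 1)
    stop("both arguments must be >= 1")
  as.numeric(barcodes_per_round)^as.numeric(rounds)
}

#' Built-in whitelist presets
#'
#' Two deterministic whitelist families ship with the package:
#' \describe{
#'   \item{`"realistic"`}{96 barcodes per round, minimum pairwise Hamming
#'     distance 3 (greedy seeded construction) — comparable in density to
#'     commercial plate sets.}
#'   \item{`"guarantee"`}{16 barcodes per round at minimum pairwise distance
#'     exactly 6, built by doubling every base of the 16 codewords of a
#'     shortened quaternary Hamming code of length 4. With separation 6, an
#'     element carrying 2 substitutions is uniquely within distance 2 of its
#'     origin and one carrying 3 substitutions is at distance >= 3 from every
#'     entry, so correction outcomes are analytically forced.}
#' }
#'
#' @param name `"realistic"` or `"guarantee"`.
#' @param bc_length Barcode length; the presets are defined for 8.
#' @return List of three [barcode_set()] objects (rounds 1..3).
#' @export
whitelist_preset <- function(name = c("realistic", "guarantee"),
                             bc_length = 8L) {
  name <- match.arg(name)
  if (name == "realistic") {
    lapply(1:3, function(r)
      generate_whitelist(96L, bc_length, min_distance = 3L,
                         seed = 7100L + r, round = r))
  } else {
    if (bc_length %% 2L != 0L)
      stop("guarantee preset requires an even bc_length")
    half <- .hamming4_code(bc_length %/% 2L)
    doubled <- half[, rep(seq_len(ncol(half)), each = 2L), drop = FALSE]
    seqs <- .int2seq(doubled + 1L)
    lapply(1:3, function(r) barcode_set(seqs, round = r))
  }
}
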