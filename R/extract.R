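# Barcode extraction strategies (fixed-position, linker-anchored, barcode
# alignment) and whitelist error correction.

.SHIFT_ORDER <- function(max_shift) {
  # preference: theoretical position first, then nearest, ties to the left
  s <- 0L
  for (k in seq_len(max_shift)) s <- c(s, -k, k)
  s
}

.empty_call <- function(n, strategy, names = NULL) {
  data.table::data.table(
    read_id = if (is.null(names)) rep(NA_character_, n) else names,
    strategy = strategy,
    status = rep("ok", n),
    umi = rep(NA_character_, n),
    bc3 = rep(NA_character_, n), bc2 = rep(NA_character_, n),
    bc1 = rep(NA_character_, n),
    bc3_off = rep(NA_integer_, n), bc2_off = rep(NA_integer_, n),
    bc1_off = rep(NA_integer_, n))
}

#' Fixed-position barcode extraction
#'
#' Slices the UMI and the three barcode elements at their theoretical layout
#' spans, the strategy used by position-based demultiplexers. Reads shorter
#' than the layout get status `too_short`.
#'
#' @param reads Character vector of barcode reads (read 2), optionally
#'   named by read id.
#' @param layout A [build_layout()] result.
#' @return `data.table` with one row per read: `read_id`, `strategy`,
#'   `status` (`ok`/`too_short`), `umi`, `bc3`, `bc2`, `bc1` and the 0-based
#'   element offsets.
#' @export
extract_fixed <- function(reads, layout) {
  stopifnot(inherits(layout, "sk_read_layout"))
  out <- .empty_call(length(reads), "fixed", names(reads))
  short <- nchar(reads) < layout$total_length
  out[short, "status"] <- "too_short"
  ok <- !short
  for (el in c("umi", "bc3", "bc2", "bc1")) {
    b <- .span_bounds(layout, el)
    data.table::set(out, which(ok), el, substring(reads[ok], b[1L], b[2L]))
    if (el != "umi")
      data.table::set(out, which(ok), paste0(el, "_off"),
                      rep(layout$spans[[el]][1L], sum(ok)))
  }
  out
}

# Hamming score of placing `pattern` at 0-based position `pos` in each read;
# Inf where the placement falls outside the read.
.place_score <- function(reads, pos, pattern) {
  len <- nchar(pattern)
  n <- length(reads)
  score <- rep(Inf, n)
  if (pos < 0L) return(score)
  valid <- nchar(reads) >= pos + len
  if (!any(valid)) return(score)
  sub <- substring(reads[valid], pos + 1L, pos + len)
  pat <- .seq2int(pattern, len)
  m <- .seq2int(sub, len)
  m[is.na(m)] <- 0L              # non-ACGT read bases mismatch everything
  d <- .rowSums(m != matrix(pat, nrow(m), len, byrow = TRUE), nrow(m), len)
  score[valid] <- d
  score
}

#' Linker-anchored barcode extraction
#'
#' Aligns the two known linker sequences against each read within
#' `max_shift` bases of their theoretical positions (Hamming score; ties
#' broken toward the theoretical position, then to the left) and re-derives
#' the element spans from the best placements: BC3 and the UMI immediately
#' precede linker 2, BC2 immediately precedes linker 1, and BC1 follows
#' linker 1. A read is `not_found` when either linker's best mismatch rate
#' exceeds `max_mismatch_rate`.
#'
#' @inheritParams extract_fixed
#' @param linker1,linker2 Linker sequences to align.
#' @param max_shift Search window around the theoretical positions, in
#'   bases (default 3).
#' @param max_mismatch_rate Maximum tolerated mismatch fraction per linker
#'   (default 0.2).
#' @return As [extract_fixed()], with statuses `ok`, `not_found`,
#'   `too_short`.
#' @export
extract_linker_aligned <- function(reads, layout, linker1, linker2,
                                   max_shift = 3L, max_mismatch_rate = 0.2) {
  stopifnot(inherits(layout, "sk_read_layout"))
  n <- length(reads)
  out <- .empty_call(n, "linker", names(reads))
  short <- nchar(reads) < layout$total_length - max_shift
  out[short, "status"] <- "too_short"

  blen <- diff(layout$spans$bc3)
  ulen <- diff(layout$spans$umi)
  shifts <- .SHIFT_ORDER(max_shift)
  place <- list()
  rate <- list()
  for (lk in c("linker1", "linker2")) {
    pattern <- if (lk == "linker1") linker1 else linker2
    theo <- layout$spans[[lk]][1L]
    best <- rep(Inf, n)
    best_pos <- rep(NA_integer_, n)
    for (sh in shifts) {
      sc <- .place_score(reads, theo + sh, pattern)
      upd <- sc < best
      best[upd] <- sc[upd]
      best_pos[upd] <- theo + sh
    }
    place[[lk]] <- best_pos
    rate[[lk]] <- best / nchar(pattern)
  }

  found <- !short &
    is.finite(rate$linker1) & is.finite(rate$linker2) &
    rate$linker1 <= max_mismatch_rate & rate$linker2 <= max_mismatch_rate
  p1 <- place$linker1
  p2 <- place$linker2
  l1len <- nchar(linker1)
  spans <- list(umi = cbind(p2 - blen - ulen, p2 - blen),
                bc3 = cbind(p2 - blen, p2),
                bc2 = cbind(p1 - blen, p1),
                bc1 = cbind(p1 + l1len, p1 + l1len + blen))
  inside <- found & spans$umi[, 1L] >= 0L & spans$bc1[, 2L] <= nchar(reads)
  out[!short & !inside, "status"] <- "not_found"
  w <- which(inside)
  for (el in names(spans)) {
    data.table::set(out, w, el,
                    substring(reads[w], spans[[el]][w, 1L] + 1L,
                              spans[[el]][w, 2L]))
    if (el != "umi")
      data.table::set(out, w, paste0(el, "_off"), spans[[el]][w, 1L])
  }
  out
}

#' Whitelist-anchored barcode alignment extraction
#'
#' For each barcode element, every whitelist sequence concatenated with an
#' `anchor_length` fragment of its adjoining linker is scored (Hamming)
#' against the read at positions within `max_shift` of the theoretical
#' span. The best-scoring unique hit within `max_mismatch` total mismatches
#' fixes the element position, and the element sequence is the read's bases
#' at that position. Equal best scores from different whitelist entries
#' leave the element unassigned with status `ambiguous`.
#'
#' @inheritParams extract_fixed
#' @param chem A [chemistry()] object supplying whitelists and linkers.
#' @param anchor_length Bases of adjoining linker used as anchor (default
#'   8; must not exceed the linker length).
#' @param max_shift Search window in bases (default 3).
#' @param max_mismatch Maximum tolerated mismatches over barcode plus
#'   anchor (default 2).
#' @return As [extract_fixed()], with statuses `ok`, `not_found`,
#'   `ambiguous`, `too_short`.
#' @export
extract_bc_aligned <- function(reads, chem, layout = build_layout(chem),
                               anchor_length = 8L, max_shift = 3L,
                               max_mismatch = 2L) {
  stopifnot(inherits(chem, "sk_chemistry"))
  if (anchor_length > min(nchar(chem$linker1), nchar(chem$linker2)))
    stop("anchor_length exceeds the adjoining linker length")
  n <- length(reads)
  out <- .empty_call(n, "bc_align", names(reads))
  short <- nchar(reads) < layout$total_length
  out[short, "status"] <- "too_short"
  blen <- chem$bc_length
  a <- as.integer(anchor_length)
  shifts <- .SHIFT_ORDER(max_shift)

  # per element: theoretical bc start, anchor pattern, anchor offset
  # relative to the bc start (anchor before or after the barcode)
  plan <- list(
    bc3 = list(theo = layout$spans$bc3[1L],
               anchor = substring(chem$linker2, 1L, a),
               anchor_rel = blen),
    bc2 = list(theo = layout$spans$bc2[1L],
               anchor = substring(chem$linker2,
                                  nchar(chem$linker2) - a + 1L,
                                  nchar(chem$linker2)),
               anchor_rel = -a),
    bc1 = list(theo = layout$spans$bc1[1L],
               anchor = substring(chem$linker1,
                                  nchar(chem$linker1) - a + 1L,
                                  nchar(chem$linker1)),
               anchor_rel = -a))
  wl_of <- list(bc3 = 3L, bc2 = 2L, bc1 = 1L)

  elem_tie <- matrix(FALSE, n, 3L, dimnames = list(NULL, names(plan)))
  elem_hit <- matrix(FALSE, n, 3L, dimnames = list(NULL, names(plan)))

  for (el in names(plan)) {
    p <- plan[[el]]
    wl <- chem$whitelists[[wl_of[[el]]]]
    wl_int <- .seq2int(wl$sequence)
    best <- rep(Inf, n)
    best_entry <- rep(NA_integer_, n)
    best_pos <- rep(NA_integer_, n)
    amb <- rep(FALSE, n)
    for (sh in shifts) {
      pos <- p$theo + sh
      anchor_sc <- .place_score(reads, pos + p$anchor_rel, p$anchor)
      valid <- is.finite(anchor_sc) & nchar(reads) >= pos + blen & pos >= 0L
      if (!any(valid)) next
      sub <- substring(reads[valid], pos + 1L, pos + blen)
      m <- .seq2int(sub, blen)
      m[is.na(m)] <- 0L            # non-ACGT mismatches everything
      D <- .hamming_cross(m, wl_int) + anchor_sc[valid]
      rmin <- do.call(pmin, as.data.frame(D))
      argmin <- max.col(-D, ties.method = "first")
      ties_here <- .rowSums(D == rmin, nrow(D), ncol(D)) > 1L
      vi <- which(valid)
      upd <- rmin < best[vi]
      i_upd <- vi[upd]
      best[i_upd] <- rmin[upd]
      best_entry[i_upd] <- argmin[upd]
      best_pos[i_upd] <- pos
      amb[i_upd] <- ties_here[upd]
      eq <- !upd & rmin == best[vi]
      i_eq <- vi[eq]
      amb[i_eq] <- amb[i_eq] | ties_here[eq] |
        best_entry[i_eq] != argmin[eq]
    }
    qual <- best <= max_mismatch
    elem_tie[, el] <- qual & amb
    hit <- qual & !amb & !short
    elem_hit[, el] <- hit
    w <- which(hit)
    data.table::set(out, w, el,
                    substring(reads[w], best_pos[w] + 1L, best_pos[w] + blen))
    data.table::set(out, w, paste0(el, "_off"), best_pos[w])
  }

  ub <- .span_bounds(layout, "umi")
  long <- which(!short)
  data.table::set(out, long, "umi", substring(reads[long], ub[1L], ub[2L]))
  all_hit <- rowSums(elem_hit) == 3L
  any_tie <- rowSums(elem_tie) > 0L
  out[!short & !all_hit & any_tie, "status"] <- "ambiguous"
  out[!short & !all_hit & !any_tie, "status"] <- "not_found"
  out
}

# ---------------------------------------------------------------------------
# Whitelist correction

#' Correct observed barcode elements against a whitelist
#'
#' Finds, for each observed sequence, the unique whitelist entry at minimal
#' distance not exceeding `max_distance`. When no entry qualifies the
#' element is `no_match`; when the minimum is attained by two or more
#' entries it is `ambiguous` (conservatively rejected rather than resolved
#' arbitrarily). The default metric is Hamming — errors on barcode reads
#' are substitutions, on which Hamming and Levenshtein agree — with
#' Levenshtein available for indel-containing input.
#'
#' @param observed Character vector of observed element sequences (`NA`
#'   allowed for missing elements).
#' @param whitelist A [barcode_set()].
#' @param max_distance Correction distance (default 2).
#' @param metric `"hamming"` or `"levenshtein"`.
#' @return `data.table` with columns `index` (whitelist index or `NA`),
#'   `distance`, `reason` (`assigned`, `no_match`, `ambiguous`, `missing`).
#' @export
correct_element <- function(observed, whitelist, max_distance = 2L,
                            metric = c("hamming", "levenshtein")) {
  metric <- match.arg(metric)
  stopifnot(inherits(whitelist, "sk_barcode_set"))
  n <- length(observed)
  res <- data.table::data.table(index = rep(NA_integer_, n),
                                distance = rep(NA_integer_, n),
                                reason = rep("missing", n))
  blen <- nchar(whitelist$sequence[1L])
  usable <- !is.na(observed)
  if (metric == "hamming") usable <- usable & nchar(observed) == blen
  w <- which(usable)
  if (length(w) == 0L) return(res)
  if (metric == "hamming") {
    m <- .seq2int(observed[w], blen)
    m[is.na(m)] <- 0L
    D <- .hamming_cross(m, .seq2int(whitelist$sequence))
  } else {
    D <- utils::adist(observed[w], whitelist$sequence)
  }
  rmin <- do.call(pmin, as.data.frame(D))
  argmin <- max.col(-D, ties.method = "first")
  ties <- .rowSums(D == rmin, nrow(D), ncol(D)) > 1L
  in_range <- rmin <= max_distance
  ok <- in_range & !ties
  res[w[ok], c("index", "distance", "reason")] <-
    list(whitelist$index[argmin[ok]], as.integer(rmin[ok]), "assigned")
  # a tied minimum only blocks correction when it lies within range
  res[w[in_range & ties], "reason"] <- "ambiguous"
  res[w[!in_range], "reason"] <- "no_match"
  res[w[!ok], "distance"] <- as.integer(rmin[!ok])
  res
}

#' Correct a raw extraction to cell-barcode indices
#'
#' Applies [correct_element()] to the three extracted elements against
#' their round whitelists. A call is `assigned` only when all three
#' elements correct uniquely within `max_distance`; otherwise it is
#' `uncorrectable` (some element has no entry in range) or `ambiguous`
#' (tied minima). Raw statuses other than `ok` propagate: `too_short` and
#' `not_found` become `not_found`, a raw `ambiguous` stays `ambiguous`.
#'
#' @param raw Extraction `data.table` from one of the `extract_*`
#'   functions.
#' @param chem The [chemistry()] whose whitelists to correct against.
#' @param max_distance Correction distance (default 2).
#' @param metric `"hamming"` or `"levenshtein"`.
#' @return `data.table` with one row per read: `read_id`, `strategy`,
#'   `status` (`assigned`, `uncorrectable`, `ambiguous`, `not_found`),
#'   `umi`, corrected indices `bc1_idx`, `bc2_idx`, `bc3_idx` and
#'   per-element distances `bc1_dist`, `bc2_dist`, `bc3_dist`.
#' @export
correct_call <- function(raw, chem, max_distance = 2L,
                         metric = c("hamming", "levenshtein")) {
  metric <- match.arg(metric)
  stopifnot(inherits(chem, "sk_chemistry"))
  n <- nrow(raw)
  out <- data.table::data.table(
    read_id = raw$read_id, strategy = raw$strategy,
    status = rep("not_found", n), umi = raw$umi,
    bc1_idx = rep(NA_integer_, n), bc2_idx = rep(NA_integer_, n),
    bc3_idx = rep(NA_integer_, n),
    bc1_dist = rep(NA_integer_, n), bc2_dist = rep(NA_integer_, n),
    bc3_dist = rep(NA_integer_, n))
  out[raw$status == "ambiguous", "status"] <- "ambiguous"
  ok <- which(raw$status == "ok")
  if (length(ok) == 0L) return(out)
  reasons <- matrix("", length(ok), 3L)
  for (r in 1:3) {
    el <- paste0("bc", r)
    cr <- correct_element(raw[[el]][ok], chem$whitelists[[r]],
                          max_distance = max_distance, metric = metric)
    data.table::set(out, ok, paste0(el, "_idx"), cr$index)
    data.table::set(out, ok, paste0(el, "_dist"), cr$distance)
    reasons[, r] <- cr$reason
  }
  assigned <- rowSums(reasons == "assigned") == 3L
  failed_hard <- rowSums(reasons == "no_match" | reasons == "missing") > 0L
  out[ok[assigned], "status"] <- "assigned"
  out[ok[!assigned & failed_hard], "status"] <- "uncorrectable"
  out[ok[!assigned & !failed_hard], "status"] <- "ambiguous"
  out
}

#' Demultiplex a barcode-read FASTQ
#'
#' Runs one extraction strategy over a read-2 FASTQ followed by whitelist
#' correction, returning the per-read assignment table.
#'
#' @param r2 Path to the barcode-read FASTQ (read 2), or a `data.table`
#'   with columns `name`, `seq` as returned by [read_fastq()].
#' @param chem A [chemistry()] object.
#' @param strategy `"fixed"`, `"linker"` or `"bc_align"`.
#' @param max_distance Correction distance (default 2).
#' @param metric Correction metric, `"hamming"` or `"levenshtein"`.
#' @param max_shift Placement search window for the aligning strategies.
#' @param max_mismatch_rate Linker mismatch budget for `"linker"`.
#' @param anchor_length,max_mismatch Parameters of `"bc_align"`.
#' @return The [correct_call()] table, one row per read.
#' @export
demux <- function(r2, chem,
                  strategy = c("fixed", "linker", "bc_align"),
                  max_distance = 2L,
                  metric = c("hamming", "levenshtein"),
                  max_shift = 3L, max_mismatch_rate = 0.2,
                  anchor_length = 8L, max_mismatch = 2L) {
  strategy <- match.arg(strategy)
  metric <- match.arg(metric)
  if (is.character(r2)) r2 <- read_fastq(r2)
  reads <- r2$seq
  names(reads) <- r2$name
  layout <- build_layout(chem)
  raw <- switch(strategy,
    fixed = extract_fixed(reads, layout),
    linker = extract_linker_aligned(reads, layout, chem$linker1,
                                    chem$linker2, max_shift = max_shift,
                                    max_mismatch_rate = max_mismatch_rate),
    bc_align = extract_bc_aligned(reads, chem, layout,
                                  anchor_length = anchor_length,
                                  max_shift = max_shift,
                                  max_mismatch = max_mismatch))
  correct_call(raw, chem, max_distance = max_distance, metric = metric)
}
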