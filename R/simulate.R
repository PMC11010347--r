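# Synthetic SPLiT-seq dataset generator: truth-labelled paired reads across
# eight error categories with a within-cell minimum-distance UMI code.

#' The eight simulated read categories
#'
#' `perfect` carries no errors; `correctable_1/2/3` carry exactly
#' `subs_correctable` substitutions in 1, 2 or all 3 barcode elements;
#' `uncorrectable_1/2/3` carry `subs_uncorrectable` substitutions likewise;
#' `random` replaces the whole barcode read with random bases.
#'
#' @format Character vector of length 8.
#' @export
SK_CATEGORIES <- c("perfect",
                   "correctable_1", "correctable_2", "correctable_3",
                   "uncorrectable_1", "uncorrectable_2", "uncorrectable_3",
                   "random")

# elements hit / substitutions per hit element, by category
.CATEGORY_PLAN <- list(
  perfect         = c(hits = 0L, subs = 0L),
  correctable_1   = c(hits = 1L, subs = NA),
  correctable_2   = c(hits = 2L, subs = NA),
  correctable_3   = c(hits = 3L, subs = NA),
  uncorrectable_1 = c(hits = 1L, subs = NA),
  uncorrectable_2 = c(hits = 2L, subs = NA),
  uncorrectable_3 = c(hits = 3L, subs = NA),
  random          = c(hits = NA, subs = NA)
)

.feature_id <- function(category) paste0("feat_", category)

#' Simulation configuration
#'
#' Defaults follow the synthetic study design: 500 cells, 10,000 reads per
#' cell, eight equally represented read categories, 120-base cDNA reads, and
#' substitution counts of 2 (correctable, at the correction boundary) and 3
#' (uncorrectable, just beyond it) per affected barcode element.
#'
#' @param n_cells Number of synthetic cells (default 500).
#' @param reads_per_cell Reads per cell (default 10,000).
#' @param chemistry A [chemistry()] object.
#' @param category_mix Proportions over the 8 categories, in the order of
#'   [SK_CATEGORIES]; must sum to 1. Default equal.
#' @param subs_correctable Substitutions per affected element for
#'   correctable categories; must be <= 2 (default 2).
#' @param subs_uncorrectable Substitutions per affected element for
#'   uncorrectable categories; must be >= 3 (default 3).
#' @param read1_length cDNA (read 1) length in bases (default 120).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return An object of class `sk_sim_config`.
#' @export
sim_config <- function(n_cells = 500L,
                       reads_per_cell = 10000L,
                       chemistry = splitkit::chemistry(),
                       category_mix = rep(1 / 8, 8),
                       subs_correctable = 2L,
                       subs_uncorrectable = 3L,
                       read1_length = 120L,
                       seed = 1L) {
  n_cells <- as.integer(n_cells)
  reads_per_cell <- as.integer(reads_per_cell)
  stopifnot(inherits(chemistry, "sk_chemistry"))
  if (n_cells < 1L || reads_per_cell < 1L)
    stop("n_cells and reads_per_cell must be >= 1")
  if (length(category_mix) != 8L || any(category_mix < 0) ||
      abs(sum(category_mix) - 1) > 1e-8)
    stop("category_mix must be 8 non-negative proportions summing to 1")
  subs_correctable <- as.integer(subs_correctable)
  subs_uncorrectable <- as.integer(subs_uncorrectable)
  if (subs_correctable < 1L || subs_correctable > 2L)
    stop("subs_correctable must be 1 or 2 (within correction distance)")
  if (subs_uncorrectable < 3L)
    stop("subs_uncorrectable must be >= 3 (beyond correction distance)")
  if (subs_uncorrectable > chemistry$bc_length)
    stop("configuration error: subs_uncorrectable exceeds barcode length")
  n_space <- prod(vapply(chemistry$whitelists, nrow, 0L))
  if (n_cells > n_space)
    stop("n_cells = ", n_cells, " exceeds the combinatorial barcode space (",
         n_space, ")")
  structure(list(n_cells = n_cells, reads_per_cell = reads_per_cell,
                 chemistry = chemistry, category_mix = category_mix,
                 subs_correctable = subs_correctable,
                 subs_uncorrectable = subs_uncorrectable,
                 read1_length = as.integer(read1_length),
                 seed = as.integer(seed)),
            class = "sk_sim_config")
}

# ---------------------------------------------------------------------------
# UMI code

# Linear or greedy code built on the *current* RNG stream.
.dna_code <- function(n, length, min_distance, max_rejects = 50000L) {
  if (n > 4^length)
    stop("capacity error: ", format(n, scientific = FALSE),
         " codewords requested but only ",
         format(4^length, scientific = FALSE), " strings of length ",
         length, " exist")
  if (min_distance == 3L) {
    r <- 2L
    while ((4^r - 1) / 3 < length) r <- r + 1L
    capacity <- 4^(length - r)
    if (length - r >= 1L && n <= capacity)
      return(.int2seq(.hamming4_code(length, n) + 1L))
    stop("capacity error: ", format(n, scientific = FALSE),
         " codewords requested but the distance-3 code of length ", length,
         " holds at most ", format(max(capacity, 0), scientific = FALSE))
  }
  # greedy rejection for other distances
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
      k <- k + 1L; acc[k, ] <- cand; rejects <- 0L
    } else {
      rejects <- rejects + 1L
      if (rejects >= max_rejects)
        stop("capacity error: gave up after ", max_rejects,
             " consecutive rejections with ", k, " of ", n,
             " codewords accepted")
    }
  }
  .int2seq(acc)
}

#' Generate a minimum-distance UMI code
#'
#' Produces `n` UMIs whose pairwise Hamming distance is at least
#' `min_distance`; the code is generated once and reused across cells (the
#' distance constraint only needs to hold within a cell). For the default
#' `min_distance = 3` the code is a seeded sample of a shortened quaternary
#' Hamming code, which packs far more codewords than greedy rejection can
#' reach (16,384 at length 10); other distances fall back to greedy
#' rejection sampling.
#'
#' @param n Number of UMIs.
#' @param length UMI length in bases (default 10).
#' @param min_distance Minimum pairwise Hamming distance (default 3).
#' @param seed Integer seed.
#' @return Character vector of `n` distinct UMIs.
#' @export
generate_umi_code <- function(n, length = 10L, min_distance = 3L, seed = 1L) {
  set.seed(seed)
  .dna_code(as.integer(n), as.integer(length), as.integer(min_distance))
}

# ---------------------------------------------------------------------------
# Error injection

# Batch core: mutate rows of an integer-encoded element matrix in place.
# rows: which rows to mutate; s: substitutions per row.
.mutate_rows <- function(m, rows, s) {
  nr <- length(rows)
  if (nr == 0L) return(m)
  len <- ncol(m)
  if (s > len)
    stop("configuration error: ", s, " substitutions requested for ",
         len, "-base elements")
  pos <- .sample_positions(nr, len, s)
  idx <- cbind(rep(rows, s), as.vector(pos))
  old <- m[idx]
  m[idx] <- ((old - 1L + sample.int(3L, nr * s, replace = TRUE)) %% 4L) + 1L
  m
}

# Decide which of the three elements each read hits (uniformly k of 3).
# Returns n x 3 logical matrix.
.hit_elements <- function(n, k) {
  H <- matrix(FALSE, n, 3L)
  if (n == 0L) return(H)
  if (k == 3L) { H[] <- TRUE; return(H) }
  pick <- .sample_positions(n, 3L, k)
  H[cbind(rep(seq_len(n), k), as.vector(pick))] <- TRUE
  H
}

#' Inject category-specific substitution errors into barcode elements
#'
#' Applies the read-category error model to one read's three true barcode
#' sequences: `perfect` leaves them untouched; `correctable_k` puts exactly
#' `subs_correctable` random substitutions (substituted base differs from
#' the original) into each of `k` uniformly chosen elements;
#' `uncorrectable_k` likewise with `subs_uncorrectable` substitutions;
#' `random` signals whole-read randomization (elements are returned
#' unchanged and `randomize_read` is set).
#'
#' @param true_elements Character vector of the three true barcode
#'   sequences, in order (bc1, bc2, bc3).
#' @param category One of [SK_CATEGORIES].
#' @param subs_correctable,subs_uncorrectable Substitutions per affected
#'   element.
#' @return List with `elements` (mutated sequences), `n_subs` (per-element
#'   substitution counts) and `randomize_read` (logical).
#' @export
inject_errors <- function(true_elements, category,
                          subs_correctable = 2L, subs_uncorrectable = 3L) {
  stopifnot(length(true_elements) == 3L, all(.is_dna(true_elements)))
  if (!category %in% SK_CATEGORIES)
    stop("unknown category: ", category)
  if (category == "random")
    return(list(elements = true_elements, n_subs = rep(NA_integer_, 3L),
                randomize_read = TRUE))
  if (category == "perfect")
    return(list(elements = true_elements, n_subs = c(0L, 0L, 0L),
                randomize_read = FALSE))
  k <- .CATEGORY_PLAN[[category]][["hits"]]
  s <- if (startsWith(category, "correctable")) as.integer(subs_correctable)
       else as.integer(subs_uncorrectable)
  hit <- .hit_elements(1L, k)[1L, ]
  out <- true_elements
  n_subs <- integer(3L)
  for (e in 1:3) {
    if (!hit[e]) next
    m <- .seq2int(out[e])
    m <- .mutate_rows(m, 1L, s)
    out[e] <- .int2seq(m)
    n_subs[e] <- s
  }
  list(elements = out, n_subs = n_subs, randomize_read = FALSE)
}

# ---------------------------------------------------------------------------
# Read composition and naming

#' Compose a barcode read from its elements
#'
#' Concatenates UMI, BC3, LINKER2, BC2, LINKER1, BC1 in layout order.
#' Vectorised over reads; all element lengths are checked against the
#' layout spans.
#'
#' @param layout A [build_layout()] result.
#' @param umi,bc3,bc2,bc1 Element sequences (character vectors, recycled to
#'   a common length).
#' @param linker1,linker2 Linker sequences.
#' @return Character vector of barcode reads of length
#'   `layout$total_length`.
#' @export
compose_read2 <- function(layout, umi, bc3, bc2, bc1, linker1, linker2) {
  stopifnot(inherits(layout, "sk_read_layout"))
  n <- max(length(umi), length(bc3), length(bc2), length(bc1))
  parts <- list(umi = rep_len(umi, n), bc3 = rep_len(bc3, n),
                linker2 = linker2, bc2 = rep_len(bc2, n),
                linker1 = linker1, bc1 = rep_len(bc1, n))
  for (nm in names(parts)) {
    want <- diff(layout$spans[[nm]])
    if (any(nchar(parts[[nm]]) != want))
      stop("element '", nm, "' has length ",
           nchar(parts[[nm]])[which(nchar(parts[[nm]]) != want)[1L]],
           " but the layout requires ", want)
  }
  paste0(parts$umi, parts$bc3, parts$linker2, parts$bc2, parts$linker1,
         parts$bc1)
}

#' Encode and parse truth-carrying read names
#'
#' Every simulated read stores its ground truth in the read name, as a
#' colon-delimited record `SK<serial>:<cell_id>:<category>:<bc1>:<bc2>:
#' <bc3>:<umi>:<feature_id>` (barcodes as 1-based whitelist indices).
#' `parse_read_name()` is the exact inverse of `encode_read_name()`.
#'
#' @param truth A data.frame with columns `cell_id`, `category`, `bc1`,
#'   `bc2`, `bc3`, `umi`, `feature_id`.
#' @param serial Integer read serial(s) for the leading tag.
#' @return `encode_read_name()`: character vector of read names.
#' @export
encode_read_name <- function(truth, serial = seq_len(nrow(truth))) {
  paste(paste0("SK", serial), truth$cell_id, truth$category,
        truth$bc1, truth$bc2, truth$bc3, truth$umi, truth$feature_id,
        sep = ":")
}

#' @rdname encode_read_name
#' @param names Character vector of read names to parse.
#' @return `parse_read_name()`: a `data.table` with columns `read_id`,
#'   `cell_id`, `category`, `bc1`, `bc2`, `bc3`, `umi`, `feature_id`.
#' @export
parse_read_name <- function(names) {
  parts <- data.table::tstrsplit(names, ":", fixed = TRUE)
  if (length(parts) != 8L)
    stop("malformed read name (expected 8 colon-delimited fields): ",
         names[1L])
  bad <- !grepl("^SK[0-9]+$", parts[[1L]])
  if (any(bad)) stop("malformed read name tag: ", names[which(bad)[1L]])
  bad <- !parts[[3L]] %in% SK_CATEGORIES
  if (any(bad)) stop("unknown read category in name: ", names[which(bad)[1L]])
  ints <- lapply(parts[c(2L, 4L, 5L, 6L)],
                 function(p) suppressWarnings(as.integer(p)))
  bad <- Reduce(`|`, lapply(ints, is.na))
  if (any(bad)) stop("non-integer truth field in name: ", names[which(bad)[1L]])
  bad <- !.is_dna(parts[[7L]])
  if (any(bad)) stop("malformed UMI in read name: ", names[which(bad)[1L]])
  data.table::data.table(read_id = names,
                         cell_id = ints[[1L]],
                         category = parts[[3L]],
                         bc1 = ints[[2L]], bc2 = ints[[3L]], bc3 = ints[[4L]],
                         umi = parts[[7L]],
                         feature_id = parts[[8L]])
}

# ---------------------------------------------------------------------------
# Feature references

# Eight mutually distant random cDNA reference sequences, one per category.
.make_features <- function(read1_length, n = 8L, max_tries = 100L) {
  min_sep <- ceiling(read1_length / 4)
  for (i in seq_len(max_tries)) {
    m <- matrix(sample.int(4L, n * read1_length, replace = TRUE),
                n, read1_length)
    seqs <- .int2seq(m)
    if (.min_pairwise_distance(seqs) >= min_sep) {
      names(seqs) <- .feature_id(SK_CATEGORIES)
      return(seqs)
    }
  }
  stop("could not generate ", n, " mutually distant feature references")
}

# ---------------------------------------------------------------------------
# Dataset simulation

.open_out <- function(path, gzip) {
  if (gzip) gzfile(path, open = "w") else file(path, open = "w")
}

#' Simulate a truth-labelled SPLiT-seq dataset
#'
#' Generates `n_cells` distinct cell-barcode triplets (distinct also after
#' random-hexamer collapsing, so each synthetic cell remains one cell in the
#' collapsed matrix) and, for each cell, `reads_per_cell` read pairs
#' partitioned across the eight categories according to `category_mix`
#' (integer remainders are assigned one read each to the leading categories
#' in order). Read 1 carries the category's reference cDNA sequence
#' unmodified; read 2 is the composed barcode read with category-specific
#' substitution errors (or, for `random`, entirely random bases). Each
#' read's ground truth is encoded in its name. Output is byte-identical for
#' a fixed configuration.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param gzip Write gzipped FASTQ (default FALSE).
#' @param write_truth Also write `truth.tsv` with the parsed truth fields
#'   (default TRUE).
#' @return Invisibly, a list with `files` (paths), `cells` (data.table of
#'   truth cell barcodes), `features` (named reference sequences) and the
#'   config.
#' @export
simulate_dataset <- function(config, out_dir, gzip = FALSE,
                             write_truth = TRUE) {
  stopifnot(inherits(config, "sk_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chem <- config$chemistry
  layout <- build_layout(chem)
  n1 <- nrow(chem$whitelists[[1L]])
  set.seed(config$seed)

  features <- .make_features(config$read1_length)

  # distinct cell triplets in the hexamer-collapsed space; each cell keeps
  # one fixed raw bc1 (a cell's transcripts are primed in a single well)
  cmap <- collapse_hexamer_index(seq_len(n1), hexamer_split = chem$hexamer_split,
                                 n_round1 = n1)
  groups <- split(seq_len(n1), cmap)
  n2 <- nrow(chem$whitelists[[2L]])
  n3 <- nrow(chem$whitelists[[3L]])
  space <- length(groups) * n2 * n3
  if (config$n_cells > space)
    stop("n_cells exceeds the collapsed combinatorial space (", space, ")")
  pick <- sample.int(space, config$n_cells)
  tri <- arrayInd(pick, c(length(groups), n2, n3))
  bc1 <- vapply(tri[, 1L], function(g) {
    members <- groups[[g]]
    if (length(members) == 1L) members else members[sample.int(length(members), 1L)]
  }, 0L)
  cells <- data.table::data.table(cell_id = seq_len(config$n_cells),
                                  bc1 = bc1, bc2 = tri[, 2L], bc3 = tri[, 3L])

  # per-cell category counts (identical for every cell)
  R <- config$reads_per_cell
  counts <- as.integer(floor(config$category_mix * R))
  rem <- R - sum(counts)
  if (rem > 0L) {
    extra <- rep_len(seq_len(8L), rem)
    counts <- counts + tabulate(extra, nbins = 8L)
  }
  cat_per_cell <- rep(SK_CATEGORIES, counts)

  # one UMI code, reused across cells
  umi_code <- .dna_code(R, chem$umi_length, min_distance = 3L)
  n_code <- length(umi_code)

  wl_int <- lapply(chem$whitelists, function(w) .seq2int(w$sequence))
  qual2 <- strrep("I", layout$total_length)
  qual1 <- strrep("I", config$read1_length)

  ext <- if (gzip) ".fastq.gz" else ".fastq"
  files <- list(r1 = file.path(out_dir, paste0("R1", ext)),
                r2 = file.path(out_dir, paste0("R2", ext)),
                features = file.path(out_dir, "features.fasta"),
                whitelists = file.path(out_dir,
                                       paste0("whitelist_round", 1:3, ".tsv")),
                truth = if (write_truth) file.path(out_dir, "truth.tsv") else NULL)

  for (r in 1:3) write_whitelist(chem$whitelists[[r]], files$whitelists[r])
  write_fasta(features, files$features)

  con1 <- .open_out(files$r1, gzip)
  con2 <- .open_out(files$r2, gzip)
  on.exit({ close(con1); close(con2) }, add = TRUE)
  if (write_truth)
    cat("read_id\tcell_id\tcategory\tbc1\tbc2\tbc3\tumi\tfeature_id\n",
        file = files$truth)

  chunk_cells <- max(1L, min(config$n_cells, 200000L %/% R))
  serial0 <- 0L
  cat_f <- factor(cat_per_cell, levels = SK_CATEGORIES)
  sub_of <- c(NA, config$subs_correctable, config$subs_correctable,
              config$subs_correctable, config$subs_uncorrectable,
              config$subs_uncorrectable, config$subs_uncorrectable, NA)
  hits_of <- c(0L, 1L, 2L, 3L, 1L, 2L, 3L, NA)

  for (c0 in seq(1L, config$n_cells, by = chunk_cells)) {
    idx <- c0:min(config$n_cells, c0 + chunk_cells - 1L)
    nc <- length(idx)
    N <- nc * R
    cell_rep <- rep(cells$cell_id[idx], each = R)
    cat_rep <- rep(cat_per_cell, times = nc)
    cat_code <- as.integer(rep(cat_f, times = nc))
    umi <- unlist(lapply(seq_len(nc), function(i)
      umi_code[sample.int(n_code, R)]), use.names = FALSE)

    bcidx <- list(rep(cells$bc1[idx], each = R),
                  rep(cells$bc2[idx], each = R),
                  rep(cells$bc3[idx], each = R))
    elem <- lapply(1:3, function(e) wl_int[[e]][bcidx[[e]], , drop = FALSE])

    # error injection, vectorised by (category class, element)
    for (cc in c(2L, 3L, 4L, 5L, 6L, 7L)) {
      rows <- which(cat_code == cc)
      if (length(rows) == 0L) next
      H <- .hit_elements(length(rows), hits_of[cc])
      s <- sub_of[cc]
      for (e in 1:3) {
        hit_rows <- rows[H[, e]]
        elem[[e]] <- .mutate_rows(elem[[e]], hit_rows, s)
      }
    }

    read2 <- compose_read2(layout,
                           umi = umi,
                           bc3 = .int2seq(elem[[3L]]),
                           bc2 = .int2seq(elem[[2L]]),
                           bc1 = .int2seq(elem[[1L]]),
                           linker1 = chem$linker1, linker2 = chem$linker2)
    rnd <- which(cat_code == 8L)
    if (length(rnd) > 0L) {
      rm_ <- matrix(sample.int(4L, length(rnd) * layout$total_length,
                               replace = TRUE),
                    length(rnd), layout$total_length)
      read2[rnd] <- .int2seq(rm_)
    }

    feature_id <- .feature_id(cat_rep)
    read1 <- unname(features[feature_id])
    truth <- data.table::data.table(cell_id = cell_rep, category = cat_rep,
                                    bc1 = bcidx[[1L]], bc2 = bcidx[[2L]],
                                    bc3 = bcidx[[3L]], umi = umi,
                                    feature_id = feature_id)
    nm <- encode_read_name(truth, serial = serial0 + seq_len(N))
    serial0 <- serial0 + N

    writeLines(as.vector(rbind(paste0("@", nm), read1, "+", qual1)), con1)
    writeLines(as.vector(rbind(paste0("@", nm), read2, "+", qual2)), con2)
    if (write_truth) {
      truth_out <- data.table::data.table(read_id = nm, truth)
      data.table::fwrite(truth_out, files$truth, sep = "\t", append = TRUE,
                         col.names = FALSE)
    }
  }

  invisible(list(files = files, cells = cells, features = features,
                 config = config))
}
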