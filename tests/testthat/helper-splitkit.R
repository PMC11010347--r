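# Shared fixtures and independent oracles for the test suite.

# Chemistry with the analytically forced whitelists (pairwise separation 6):
# 2-substitution elements must correct uniquely, 3-substitution elements
# must fail for every entry.
guarantee_chem <- function(version = "v2") {
  chemistry(version, whitelists = whitelist_preset("guarantee"),
            hexamer_split = 8L)
}

tiny_config <- function(n_cells = 4L, reads_per_cell = 80L, seed = 11L,
                        chem = guarantee_chem(), ...) {
  sim_config(n_cells = n_cells, reads_per_cell = reads_per_cell,
             chemistry = chem, seed = seed, ...)
}

# --- independent oracles ---------------------------------------------------

# character-by-character Hamming distance, independent of the package's
# integer-matrix implementation
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

# textbook dynamic-programming Levenshtein distance
oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, integer(m))
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[m + 1]
}

# brute-force unique-minimum whitelist scan
oracle_correct <- function(observed, whitelist_seqs, max_distance = 2,
                           metric = c("hamming", "levenshtein")) {
  metric <- match.arg(metric)
  f <- if (metric == "hamming") oracle_hamming else oracle_levenshtein
  d <- vapply(whitelist_seqs, function(w) f(observed, w), 0)
  dmin <- min(d)
  if (dmin > max_distance || sum(d == dmin) > 1)
    return(list(index = NA_integer_, distance = NA_integer_))
  list(index = as.integer(which.min(d)), distance = as.integer(dmin))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
           collapse = ""), "")
}

# substitute exactly k positions of a DNA string (new base != old)
mutate_dna <- function(x, k) {
  ch <- strsplit(x, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste0(ch, collapse = "")
}
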