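test_that("hamming and levenshtein distances match independent computations", {
  expect_identical(hamming("AAAA", "AAAT"), 1L)
  expect_identical(hamming("ACGT", "ACGT"), 0L)
  expect_error(hamming("AA", "A"), "equal-length")
  expect_identical(levenshtein("kitten", "sitting"), 3L)
  expect_identical(levenshtein("ACGT", "ACGT"), 0L)
  expect_identical(levenshtein("", "AB"), 2L)
  set.seed(12)
  # hamming >= levenshtein on equal-length strings; equality for at most
  # one substitution (several substitutions can mimic a cheaper shift)
  for (i in 1:25) {
    a <- random_dna(1, 12)
    b <- mutate_dna(a, sample(0:4, 1))
    expect_gte(hamming(a, b), levenshtein(a, b))
    b1 <- mutate_dna(a, 1)
    expect_identical(hamming(a, b1), levenshtein(a, b1))
    expect_identical(hamming(a, b), oracle_hamming(a, b))
    c <- random_dna(1, 12)
    expect_gte(hamming(a, c), levenshtein(a, c))
    expect_identical(levenshtein(a, c), as.integer(oracle_levenshtein(a, c)))
  }
})

test_that("fixed extraction slices purely by position", {
  chem <- chemistry("v2")
  layout <- build_layout(chem)
  set.seed(8)
  umi <- random_dna(1, 10); b3 <- random_dna(1, 8)
  b2 <- random_dna(1, 8); b1 <- random_dna(1, 8)
  read <- compose_read2(layout, umi, b3, b2, b1, chem$linker1, chem$linker2)
  call <- extract_fixed(read, layout)
  expect_identical(call$status, "ok")
  expect_identical(unlist(call[, c("umi", "bc3", "bc2", "bc1")]),
                   c(umi = umi, bc3 = b3, bc2 = b2, bc1 = b1))
  expect_identical(c(call$bc3_off, call$bc2_off, call$bc1_off),
                   c(10L, 48L, 78L))

  short <- substring(read, 1, layout$total_length - 1)
  expect_identical(extract_fixed(short, layout)$status, "too_short")

  # substitutions inside bc2 come back verbatim at the same span
  b2mut <- mutate_dna(b2, 2)
  readm <- compose_read2(layout, umi, b3, b2mut, b1,
                         chem$linker1, chem$linker2)
  expect_identical(extract_fixed(readm, layout)$bc2, b2mut)
})

test_that("linker-aligned extraction recovers position-shifted reads", {
  chem <- guarantee_chem()
  layout <- build_layout(chem)
  cfg <- tiny_config(n_cells = 3, reads_per_cell = 160, seed = 13)
  d <- withr::local_tempdir()
  simulate_dataset(cfg, d)
  r2 <- read_fastq(file.path(d, "R2.fastq"))
  truth <- parse_read_name(r2$name)
  reads <- r2$seq

  fx <- extract_fixed(reads, layout)
  lk <- extract_linker_aligned(reads, layout, chem$linker1, chem$linker2)
  sub_only <- truth$category != "random"
  # substitution-only reads: identical element sequences to fixed slicing
  for (el in c("umi", "bc3", "bc2", "bc1"))
    expect_identical(lk[[el]][sub_only], fx[[el]][sub_only])
  expect_true(all(lk$status[sub_only] == "ok"))
  # fully random barcode reads should almost never present two linkers
  expect_gt(mean(lk$status[!sub_only] == "not_found"), 0.95)

  # one base prepended: fixed slicing shifts, linker alignment recovers
  i <- which(truth$category == "perfect")[1]
  shifted <- paste0("G", reads[i])
  fx1 <- extract_fixed(shifted, layout)
  lk1 <- extract_linker_aligned(shifted, layout, chem$linker1, chem$linker2)
  wl <- chem$whitelists
  truth_b1 <- wl[[1]]$sequence[truth$bc1[i]]
  expect_false(identical(fx1$bc1, truth_b1))
  expect_identical(lk1$bc1, truth_b1)
  expect_identical(lk1$bc2, wl[[2]]$sequence[truth$bc2[i]])
  expect_identical(lk1$bc3, wl[[3]]$sequence[truth$bc3[i]])
  expect_identical(lk1$umi, truth$umi[i])
  expect_identical(c(lk1$bc3_off, lk1$bc2_off, lk1$bc1_off),
                   c(11L, 49L, 79L))
})

test_that("whitelist-anchored alignment finds truth elements and rejects ties", {
  chem <- guarantee_chem()
  layout <- build_layout(chem)
  set.seed(14)
  wl <- chem$whitelists
  b1 <- wl[[1]]$sequence[3]; b2 <- wl[[2]]$sequence[5]
  b3 <- wl[[3]]$sequence[9]
  umi <- random_dna(1, 10)
  read <- compose_read2(layout, umi, b3, b2, b1, chem$linker1, chem$linker2)
  call <- extract_bc_aligned(read, chem, layout)
  expect_identical(call$status, "ok")
  expect_identical(c(call$bc1, call$bc2, call$bc3), c(b1, b2, b3))

  # an observed bc2 equidistant from two whitelist entries is left null
  tie_wl <- lapply(1:3, function(r) barcode_set(c("AAAAAAAA", "AAAATTTT",
                                                  "GGGGGGGG", "CCCCCCCC"),
                                                round = r))
  tchem <- chemistry("v2", whitelists = tie_wl, hexamer_split = 2L)
  tlay <- build_layout(tchem)
  tread <- compose_read2(tlay, umi, "GGGGGGGG", "AAAAAATT", "CCCCCCCC",
                         tchem$linker1, tchem$linker2)
  tcall <- extract_bc_aligned(tread, tchem, tlay, max_mismatch = 2)
  expect_true(is.na(tcall$bc2))
  expect_identical(tcall$status, "ambiguous")

  # correctable categories under the guarantee whitelist resolve to truth
  cfg <- tiny_config(n_cells = 2, reads_per_cell = 80, seed = 15)
  d <- withr::local_tempdir()
  simulate_dataset(cfg, d)
  r2 <- read_fastq(file.path(d, "R2.fastq"))
  truth <- parse_read_name(r2$name)
  keep <- truth$category %in% c("perfect", "correctable_1", "correctable_2",
                                "correctable_3")
  calls <- correct_call(extract_bc_aligned(r2$seq[keep], chem, layout),
                        chem)
  expect_true(all(calls$status == "assigned"))
  expect_identical(calls$bc1_idx, truth$bc1[keep])
  expect_identical(calls$bc2_idx, truth$bc2[keep])
  expect_identical(calls$bc3_idx, truth$bc3[keep])
})

test_that("correct_element agrees exactly with a brute-force oracle", {
  # spec'd constructed examples
  wl4 <- barcode_set(c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT"))
  r <- correct_element("AAAAAATT", wl4)
  expect_identical(r$index, 1L)
  expect_identical(r$distance, 2L)
  expect_identical(correct_element("AAAAATTT", wl4)$reason, "no_match")
  tie <- correct_element("AACCAAAA",
                         barcode_set(c("AAAAAAAA", "CCCCAAAA")))
  expect_identical(tie$reason, "ambiguous")
  expect_true(is.na(tie$index))

  # randomised equivalence, hamming metric: 10^4 instances
  set.seed(16)
  wl <- generate_whitelist(24, 8, 3, seed = 17)
  obs <- character(10000)
  obs[1:4000] <- random_dna(4000, 8)
  obs[4001:10000] <- vapply(sample(wl$sequence, 6000, TRUE),
                            function(s) mutate_dna(s, sample(0:4, 1)), "",
                            USE.NAMES = FALSE)
  got <- correct_element(obs, wl, max_distance = 2, metric = "hamming")
  want_idx <- integer(10000); want_d <- integer(10000)
  for (i in seq_len(10000)) {
    o <- oracle_correct(obs[i], wl$sequence, 2, "hamming")
    want_idx[i] <- o$index; want_d[i] <- o$distance
  }
  expect_identical(got$index, want_idx)
  expect_identical(got$distance[got$reason == "assigned"],
                   want_d[!is.na(want_idx)])

  # levenshtein metric against the DP oracle (smaller sample)
  obs_l <- obs[seq(1, 10000, by = 10)]
  got_l <- correct_element(obs_l, wl, max_distance = 2,
                           metric = "levenshtein")
  for (i in seq_along(obs_l)) {
    o <- oracle_correct(obs_l[i], wl$sequence, 2, "levenshtein")
    expect_identical(got_l$index[i], o$index)
  }
})

test_that("correct_call outcomes are forced by category under the guarantee whitelist", {
  chem <- guarantee_chem()
  layout <- build_layout(chem)
  set.seed(18)
  wl <- chem$whitelists
  for (rep in 1:10) {
    idx <- vapply(1:3, function(r) sample(nrow(wl[[r]]), 1), 0L)
    truth_el <- vapply(1:3, function(r) wl[[r]]$sequence[idx[r]], "")
    umi <- random_dna(1, 10)

    mk_call <- function(elements) {
      read <- compose_read2(layout, umi, elements[3], elements[2],
                            elements[1], chem$linker1, chem$linker2)
      correct_call(extract_fixed(read, layout), chem)
    }
    perf <- mk_call(truth_el)
    expect_identical(perf$status, "assigned")
    expect_identical(c(perf$bc1_dist, perf$bc2_dist, perf$bc3_dist),
                     c(0L, 0L, 0L))

    corr3 <- mk_call(inject_errors(truth_el, "correctable_3")$elements)
    expect_identical(corr3$status, "assigned")
    expect_identical(c(corr3$bc1_idx, corr3$bc2_idx, corr3$bc3_idx),
                     c(idx[1], idx[2], idx[3]))
    expect_identical(c(corr3$bc1_dist, corr3$bc2_dist, corr3$bc3_dist),
                     c(2L, 2L, 2L))

    unc1 <- mk_call(inject_errors(truth_el, "uncorrectable_1")$elements)
    expect_identical(unc1$status, "uncorrectable")
  }
  # raw failures propagate
  short <- correct_call(extract_fixed("ACGT", layout), chem)
  expect_identical(short$status, "not_found")
})
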