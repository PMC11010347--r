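test_that("UMI codes satisfy the pairwise distance constraint at every size", {
  for (n in c(1, 3, 50, 200)) {
    u <- generate_umi_code(n, length = 10, min_distance = 3, seed = 9)
    expect_length(u, n)
    expect_length(unique(u), n)
    if (n > 1 && n <= 50) {
      dmin <- Inf
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        dmin <- min(dmin, oracle_hamming(u[i], u[j]))
      expect_gte(dmin, 3)
    }
  }
  # same seed, same code
  expect_identical(generate_umi_code(100, 10, 3, seed = 2),
                   generate_umi_code(100, 10, 3, seed = 2))
  # pigeonhole: more codewords than strings of that length
  expect_error(generate_umi_code(4^4 + 1, length = 4), "capacity")
  # greedy fallback for other distances still audits clean
  u2 <- generate_umi_code(20, 8, min_distance = 2, seed = 3)
  dmin <- Inf
  for (i in 1:19) for (j in (i + 1):20)
    dmin <- min(dmin, oracle_hamming(u2[i], u2[j]))
  expect_gte(dmin, 2)
})

test_that("error injection mutates exactly the categorised elements and bases", {
  set.seed(21)
  wl <- whitelist_preset("realistic")
  plan <- list(perfect = c(0, 0), correctable_1 = c(1, 2),
               correctable_2 = c(2, 2), correctable_3 = c(3, 2),
               uncorrectable_1 = c(1, 3), uncorrectable_2 = c(2, 3),
               uncorrectable_3 = c(3, 3))
  for (cat in names(plan)) {
    k <- plan[[cat]][1]; s <- plan[[cat]][2]
    for (rep in 1:20) {
      truth <- vapply(1:3, function(r) sample(wl[[r]]$sequence, 1), "")
      out <- inject_errors(truth, cat)
      expect_false(out$randomize_read)
      d <- mapply(oracle_hamming, out$elements, truth)
      expect_equal(sum(d > 0), k)
      expect_true(all(d[d > 0] == s))
      expect_equal(out$n_subs[d > 0], rep(s, k), ignore_attr = TRUE)
    }
  }
  rnd <- inject_errors(c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"), "random")
  expect_true(rnd$randomize_read)
  expect_error(inject_errors(c("ACGT", "ACGT", "ACGT"), "uncorrectable_1",
                             subs_uncorrectable = 5),
               "configuration error")
  expect_error(inject_errors(c("ACGT", "ACGT", "ACGT"), "nonsense"),
               "category")
})

test_that("read names encode truth and parse back exactly", {
  set.seed(33)
  truth <- data.frame(cell_id = sample(500, 20),
                      category = sample(SK_CATEGORIES, 20, replace = TRUE),
                      bc1 = sample(96, 20, TRUE), bc2 = sample(96, 20, TRUE),
                      bc3 = sample(96, 20, TRUE),
                      umi = random_dna(20, 10),
                      feature_id = paste0("feat_", sample(8, 20, TRUE)))
  nm <- encode_read_name(truth, serial = 1:20)
  back <- parse_read_name(nm)
  for (col in names(truth))
    expect_equal(back[[col]], truth[[col]], ignore_attr = TRUE)
  expect_error(parse_read_name("SK1:2:perfect:1:2"), "8 colon")
  expect_error(parse_read_name("SK1:2:bogus:1:2:3:ACGTACGTAC:f"),
               "category")
  expect_error(parse_read_name("XX1:2:perfect:1:2:3:ACGTACGTAC:f"), "tag")
})

test_that("compose_read2 validates element lengths against the layout", {
  chem <- chemistry("v2")
  layout <- build_layout(chem)
  r <- compose_read2(layout, strrep("A", 10), strrep("C", 8), strrep("G", 8),
                     strrep("T", 8), chem$linker1, chem$linker2)
  expect_equal(nchar(r), 86)
  expect_error(
    compose_read2(layout, strrep("A", 10), strrep("C", 8), strrep("G", 8),
                  strrep("T", 7), chem$linker1, chem$linker2),
    "'bc1'")
})

test_that("simulated datasets are deterministic and structurally sound", {
  cfg <- sim_config(n_cells = 2, reads_per_cell = 16,
                    chemistry = guarantee_chem(), seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res1 <- simulate_dataset(cfg, d1)
  res2 <- simulate_dataset(cfg, d2)
  for (f in c("R1.fastq", "R2.fastq", "truth.tsv", "features.fasta"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))

  r2 <- read_fastq(file.path(d1, "R2.fastq"))
  expect_equal(nrow(r2), 32)
  truth <- parse_read_name(r2$name)
  # 2 distinct truth cell triplets; 2 reads per category per cell
  expect_equal(nrow(unique(truth[, c("bc1", "bc2", "bc3")])), 2)
  expect_true(all(table(truth$category, truth$cell_id) == 2))

  # linker spans untouched on every non-random read
  chem <- cfg$chemistry
  layout <- build_layout(chem)
  nonrand <- r2$seq[truth$category != "random"]
  l1 <- substring(nonrand, layout$spans$linker1[1] + 1, layout$spans$linker1[2])
  l2 <- substring(nonrand, layout$spans$linker2[1] + 1, layout$spans$linker2[2])
  expect_true(all(l1 == chem$linker1))
  expect_true(all(l2 == chem$linker2))

  # within-cell UMIs distinct and pairwise Hamming >= 3
  for (cid in unique(truth$cell_id)) {
    u <- truth$umi[truth$cell_id == cid]
    expect_length(unique(u), length(u))
    dmin <- Inf
    for (i in seq_len(length(u) - 1)) for (j in (i + 1):length(u))
      dmin <- min(dmin, oracle_hamming(u[i], u[j]))
    expect_gte(dmin, 3)
  }

  # per-element substitution distances from truth match the category plan
  wl <- chem$whitelists
  el <- list(bc1 = substring(r2$seq, layout$spans$bc1[1] + 1, layout$spans$bc1[2]),
             bc2 = substring(r2$seq, layout$spans$bc2[1] + 1, layout$spans$bc2[2]),
             bc3 = substring(r2$seq, layout$spans$bc3[1] + 1, layout$spans$bc3[2]))
  for (i in which(truth$category != "random")) {
    d <- vapply(1:3, function(r)
      oracle_hamming(el[[paste0("bc", r)]][i],
                     wl[[r]]$sequence[truth[[paste0("bc", r)]][i]]), 0)
    cat_i <- truth$category[i]
    exp_hits <- switch(sub("_.*", "", cat_i), perfect = 0,
                       correctable = as.integer(sub(".*_", "", cat_i)),
                       uncorrectable = as.integer(sub(".*_", "", cat_i)))
    exp_sub <- if (startsWith(cat_i, "correctable")) 2 else 3
    expect_equal(sum(d > 0), exp_hits)
    if (exp_hits > 0) expect_true(all(d[d > 0] == exp_sub))
  }

  # category remainder is assigned round-robin in category order
  cfg20 <- sim_config(n_cells = 1, reads_per_cell = 20,
                      chemistry = guarantee_chem(), seed = 6)
  d3 <- withr::local_tempdir()
  simulate_dataset(cfg20, d3)
  tr <- parse_read_name(read_fastq(file.path(d3, "R2.fastq"))$name)
  counts <- table(factor(tr$category, levels = SK_CATEGORIES))
  expect_equal(as.integer(counts), c(3, 3, 3, 3, 2, 2, 2, 2))
})

test_that("feature references are mutually distant and written as FASTA", {
  cfg <- tiny_config(n_cells = 2, reads_per_cell = 8, seed = 7)
  d <- withr::local_tempdir()
  res <- simulate_dataset(cfg, d)
  feats <- read_fasta(file.path(d, "features.fasta"))
  expect_length(feats, 8)
  expect_identical(sort(names(feats)), sort(paste0("feat_", SK_CATEGORIES)))
  expect_true(all(nchar(feats) == 120))
  dmin <- Inf
  for (i in 1:7) for (j in (i + 1):8)
    dmin <- min(dmin, oracle_hamming(feats[[i]], feats[[j]]))
  expect_gte(dmin, 30)
})
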