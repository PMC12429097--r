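test_that("fixed seeds reproduce every generated artefact byte-for-byte", {
  cfg <- generator_config(seed = 42)
  a <- generate_variant_table(cfg)
  b <- generate_variant_table(cfg)
  expect_identical(a, b)

  ta <- generate_ddg_tables(cfg, a$truth)
  tb <- generate_ddg_tables(cfg, b$truth)
  expect_identical(ta, tb)

  sa <- generate_sequences(cfg, n_sequences = 5, seq_length = 80)
  sb <- generate_sequences(cfg, n_sequences = 5, seq_length = 80)
  expect_identical(sa, sb)

  other <- generate_variant_table(generator_config(seed = 43))
  expect_false(identical(a$reference, other$reference))
})

test_that("variant tables honour configured tallies and placement", {
  vt <- generate_variant_table(generator_config(seed = 1))
  expect_equal(nrow(vt$variants), 112L)
  expect_equal(summarize_categories(vt$variants),
               cdkl5_category_counts("kinase"))
  expect_true(all(vt$variants$pos >= 1 & vt$variants$pos <= 302))
  # wild-type residues agree with the generated reference
  expect_equal(vt$variants$ref,
               substring(vt$reference, vt$variants$pos, vt$variants$pos))
  # protein-level changes are unique
  expect_false(any(duplicated(vt$truth$variant)))

  empty <- generate_variant_table(
    generator_config(seed = 1, category_counts = c(benign = 0))
  )
  expect_equal(nrow(empty$variants), 0L)

  expect_error(
    generate_variant_table(
      generator_config(seed = 1, category_counts = c(benign = 10000))
    ),
    "exceed"
  )
})

test_that("zero noise collapses every ddG cell onto its class mean", {
  cfg <- generator_config(seed = 2, noise_sd = 0,
                          category_counts = c(benign = 3, pathogenic = 3))
  vt <- generate_variant_table(cfg)
  tabs <- generate_ddg_tables(cfg, vt$truth)

  fm <- cfg$folding_class_means
  truth_class <- setNames(vt$truth$true_class, vt$truth$variant)
  for (i in seq_len(nrow(tabs$folding))) {
    row <- tabs$folding[i, ]
    expected <- fm[[truth_class[[row$variant]]]][fm$method == row$method]
    expect_equal(row$ddg, expected)
  }

  bm <- cfg$binding_class_means
  key <- paste(tabs$binding$method, tabs$binding$complex)
  mkey <- paste(bm$method, bm$complex)
  expected_b <- ifelse(truth_class[tabs$binding$variant] == "benign",
                       setNames(bm$benign, mkey)[key],
                       setNames(bm$pathogenic, mkey)[key])
  expect_equal(tabs$binding$ddg, unname(expected_b))
})

test_that("generated ddG tables recover configured class means at n = 500", {
  cfg <- generator_config(seed = 7,
                          category_counts = c(benign = 500,
                                              pathogenic = 500))
  vt <- generate_variant_table(cfg)
  tabs <- generate_ddg_tables(cfg, vt$truth)
  labels <- setNames(vt$truth$true_class, vt$truth$variant)

  bsum <- class_summary(tabs$binding, labels)
  bm <- cfg$binding_class_means
  for (i in seq_len(nrow(bm))) {
    for (cls in c("benign", "pathogenic")) {
      row <- bsum[bsum$method == bm$method[i] &
                    bsum$complex == bm$complex[i] & bsum$class == cls, ]
      se <- row$sd / sqrt(row$n)
      expect_lt(abs(row$mean - bm[[cls]][i]), 3 * se)
    }
  }
})

test_that("separable mode plants a recoverable threshold", {
  cfg <- generator_config(seed = 5, separable = TRUE)
  vt <- generate_variant_table(cfg)
  tabs <- generate_ddg_tables(cfg, vt$truth)
  agg <- aggregate_ddg(tabs$folding, tabs$binding)

  stat <- setNames(agg$ddg_fmax, agg$variant)[vt$truth$variant]
  cats <- setNames(vt$truth$category, vt$truth$variant)
  strict <- cats %in% c("benign", "pathogenic")
  model <- derive_threshold(stat[strict], cats[strict], "ddg_fmax")
  expect_true(model$separable)
  expect_equal(model$midpoint, 0.77, tolerance = 1e-8)
  expect_lte(model$min_pathogenic - model$max_benign, cfg$gap + 1e-8)

  # every variant lands on its true side of the planted cutoff
  truth_class <- setNames(vt$truth$true_class, vt$truth$variant)
  expect_equal(unname(classify(stat, model)),
               unname(truth_class[names(stat)]))
})

test_that("planted motifs are all recovered at the configured S/T ratio", {
  cfg <- generator_config(seed = 13)
  gen <- generate_sequences(cfg, n_sequences = 60, seq_length = 120)
  hits <- purrr::imap(gen$sequences, function(s, id) {
    scan_consensus(s, sequence_id = id)
  }) |> dplyr::bind_rows()

  # recall 1.0 and precision 1.0 by construction
  expect_equal(nrow(hits), nrow(gen$truth))
  expect_equal(
    dplyr::arrange(hits[, c("seq_id", "pos")], seq_id, pos),
    dplyr::arrange(gen$truth[, c("seq_id", "pos")], seq_id, pos)
  )
  expect_equal(
    setNames(hits$residue[order(hits$seq_id, hits$pos)], NULL),
    gen$truth$residue[order(gen$truth$seq_id, gen$truth$pos)]
  )

  all_ser <- generate_sequences(
    generator_config(seed = 13, ser_thr_ratio = c(serine = 1, threonine = 0)),
    n_sequences = 20, seq_length = 80
  )
  expect_true(all(all_ser$truth$residue == "S"))

  # planted serine fraction within the binomial 99% interval of 0.85
  many <- generate_sequences(generator_config(seed = 17),
                             n_sequences = 150, seq_length = 60,
                             sites_per_seq = 2)
  n_sites <- nrow(many$truth)
  frac <- mean(many$truth$residue == "S")
  half_width <- 2.58 * sqrt(0.85 * 0.15 / n_sites)
  expect_lt(abs(frac - 0.85), half_width)

  expect_error(
    generate_sequences(cfg, n_sequences = 1, seq_length = 20,
                       sites_per_seq = 5),
    "infeasible"
  )
})

test_that("source exports reproduce the planted curation arithmetic", {
  cfg <- generator_config(seed = 23)
  exports <- generate_source_exports(cfg)

  expect_equal(nrow(exports$clinvar), 123L)  # 120 + 1 duplicate + 2 noise
  expect_equal(nrow(exports$kgp), 12L)
  expect_equal(nrow(exports$literature), 30L)

  dir <- withr::local_tempdir()
  write_source_exports(exports, dir)
  sources <- list(
    clinvar = read_source_export(file.path(dir, "clinvar.tsv")),
    kgp = read_source_export(file.path(dir, "kgp.tsv")),
    literature = read_source_export(file.path(dir, "literature.tsv"))
  )
  reference <- as.character(
    Biostrings::readAAStringSet(file.path(dir, "reference.fasta"))[[1]]
  )
  expect_equal(reference, exports$reference)

  suppressMessages({
    curated <- curate_variants(sources, reference)
  })
  expect_equal(nrow(curated$variants), 156L)
  expect_equal(nrow(curated$discarded), 2L)
  expect_setequal(
    variant_id(curated$discarded$ref, curated$discarded$pos,
               curated$discarded$alt),
    exports$truth$mismatch_ids
  )
  # the four planted overlaps carry two-source provenance
  overlaps <- curated$variants[curated$variants$sources == "clinvar,kgp", ]
  expect_equal(nrow(overlaps), 4L)
  expect_setequal(
    variant_id(overlaps$ref, overlaps$pos, overlaps$alt),
    exports$truth$overlap_ids
  )
  expect_equal(sum(summarize_categories(curated$variants)), 156L)
})
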