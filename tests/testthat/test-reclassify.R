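test_that("midpoint thresholds reproduce the published cutoffs", {
  fold <- derive_threshold(
    c(a = 0.09, b = 0.68, c = 0.86, d = 3.42),
    c(a = "benign", b = "benign", c = "pathogenic", d = "pathogenic"),
    statistic = "ddg_fmax"
  )
  expect_equal(fold$midpoint, 0.77)
  expect_true(fold$separable)

  bind <- derive_threshold(
    c(a = 0.45, b = 0.82, c = 0.95, d = 1.55),
    c(a = "benign", b = "benign", c = "pathogenic", d = "pathogenic"),
    statistic = "ddg_bmax"
  )
  expect_equal(bind$midpoint, 0.885)
  expect_equal(threshold_display(bind), 0.88)

  overlap <- derive_threshold(c(a = 1.0, b = 0.9),
                              c(a = "benign", b = "pathogenic"))
  expect_false(overlap$separable)
  expect_error(classify(1, overlap), "not separable")

  expect_error(
    derive_threshold(c(a = 1), c(a = "likely_benign")),
    "non-strict"
  )
  expect_error(
    derive_threshold(c(a = 1, b = 2), c(a = "benign", b = "benign")),
    "both a benign and a pathogenic"
  )
})

test_that("classification is strict-above-midpoint with benign boundary", {
  model <- derive_threshold(c(a = 0.68, b = 0.86),
                            c(a = "benign", b = "pathogenic"))
  expect_equal(model$midpoint, 0.77)
  expect_equal(classify(c(3.42, 0.09, 0.77), model),
               c("pathogenic", "benign", "benign"))
  expect_error(classify(NA_real_, model), "missing")
})

test_that("thresholds are equivariant under positive affine scaling", {
  set.seed(14)
  for (i in 1:20) {
    nb <- sample(2:6, 1)
    np <- sample(2:8, 1)
    benign <- runif(nb, 0, 0.7)
    pathogenic <- runif(np, 0.8, 4)
    values <- c(benign, pathogenic)
    names(values) <- paste0("v", seq_along(values))
    labels <- setNames(rep(c("benign", "pathogenic"), c(nb, np)),
                       names(values))
    model <- derive_threshold(values, labels)
    c_scale <- runif(1, 0.1, 10)
    scaled <- derive_threshold(values * c_scale, labels)
    expect_equal(scaled$midpoint, model$midpoint * c_scale)
    expect_equal(classify(values * c_scale, scaled),
                 classify(values, model))
    # training-set consistency: every training label is reproduced
    expect_equal(unname(classify(values, model)), unname(labels))
  }
})

test_that("redistribution marginals equal the original category counts", {
  set.seed(8)
  cats <- sample(germline_levels(), 60, replace = TRUE)
  names(cats) <- paste0("V", seq_along(cats), "A")
  calls <- setNames(sample(c("benign", "pathogenic"), 60, replace = TRUE),
                    names(cats))
  mat <- redistribute(cats, calls)
  row_sums <- mat$benign + mat$pathogenic
  expect_equal(setNames(row_sums, mat$category),
               table(cats)[mat$category] |> as.integer() |>
                 setNames(mat$category))
  expect_equal(sum(row_sums), length(cats))

  all_path <- setNames(rep("pathogenic", 60), names(cats))
  mat2 <- redistribute(cats, all_path)
  expect_true(all(mat2$benign == 0))
  expect_equal(sum(mat2$pathogenic), 60L)

  empty <- redistribute(setNames(character(0), character(0)),
                        setNames(character(0), character(0)))
  expect_equal(nrow(empty), 0L)

  expect_error(
    redistribute(c(A1V = "benign"),
                 c(A1V = "benign", C2Y = "pathogenic")),
    "not in original"
  )
})

test_that("mechanism partition is disjoint, exhaustive, with ties to binding", {
  agg <- tibble::tibble(
    variant = c("A10V", "C20Y", "D30G"),
    ddg_fmax = c(1.0, 0.5, 0.4),
    ddg_bmax = c(0.5, 0.5, 0.9)
  )
  part <- partition_mechanism(agg)
  expect_equal(part$folding_dominant$variant, "A10V")
  expect_equal(part$binding_dominant$variant, c("C20Y", "D30G"))
  expect_equal(sort(c(part$folding_dominant$variant,
                      part$binding_dominant$variant)),
               sort(agg$variant))
  expect_length(intersect(part$folding_dominant$variant,
                          part$binding_dominant$variant), 0)
  expect_error(
    partition_mechanism(tibble::tibble(variant = "A1V", ddg_fmax = 1,
                                       ddg_bmax = NA_real_)),
    "present"
  )
})

test_that("published mechanism lists partition into 86 folding and 17 binding", {
  mech <- cdkl5_mechanism_variants()
  # encode membership as a consistent pair of statistics and re-derive it
  agg <- tibble::tibble(
    variant = mech$variant,
    ddg_fmax = ifelse(mech$mechanism == "folding", 1.5, 0.6),
    ddg_bmax = ifelse(mech$mechanism == "folding", 0.6, 1.5)
  )
  part <- partition_mechanism(agg)
  expect_equal(nrow(part$folding_dominant), 86L)
  expect_equal(nrow(part$binding_dominant), 17L)
  expect_equal(nrow(part$folding_dominant) + nrow(part$binding_dominant),
               103L)
  # sorted by residue position
  pos <- parse_protein_change(part$folding_dominant$variant)$pos
  expect_true(!is.unsorted(pos))
})

test_that("end-to-end reclassification keeps strict labels in separable mode", {
  cfg <- generator_config(seed = 99, separable = TRUE)
  vt <- generate_variant_table(cfg)
  tabs <- generate_ddg_tables(cfg, vt$truth)
  agg <- aggregate_ddg(tabs$folding, tabs$binding)

  for (stat in c("ddg_fmax", "ddg_bmax")) {
    res <- reclassify_variants(agg, vt$variants, statistic = stat)
    expect_true(res$model$separable)
    planted <- cfg$planted_threshold[[stat]]
    expect_equal(res$model$midpoint, planted, tolerance = 1e-8)

    # every variant call matches the generator's true class
    truth <- setNames(vt$truth$true_class, vt$truth$variant)
    expect_equal(unname(truth[res$calls$variant]), res$calls$new_call)

    # redistribution marginals conserve the category tallies
    redis <- res$redistribution
    counts <- summarize_categories(vt$variants)
    for (i in seq_len(nrow(redis))) {
      expect_equal(redis$benign[i] + redis$pathogenic[i],
                   unname(counts[redis$category[i]]))
    }
  }
})
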