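test_that("protein-change tokens parse in compact and HGVS forms", {
  p <- parse_protein_change(c("R178Q", "p.Arg59*", "p.Arg59Pro", "L302F"))
  expect_equal(p$ref, c("R", "R", "R", "L"))
  expect_equal(p$pos, c(178L, 59L, 59L, 302L))
  expect_equal(p$alt, c("Q", "*", "P", "F"))
  expect_equal(p$missense, c(TRUE, FALSE, TRUE, TRUE))

  expect_error(parse_protein_change("R0Q"), "position")
  expect_error(parse_protein_change("Xyz12Ala"), "residue")
  expect_error(parse_protein_change("not-a-variant"), "malformed")
  expect_error(parse_protein_change("R178R"), "identical")
})

test_that("germline category strings harmonize case- and punctuation-tolerantly", {
  expect_equal(
    normalize_category(c(
      "Benign", "Likely benign", "Benign/Likely benign",
      "Uncertain significance",
      "Conflicting classifications of pathogenicity",
      "conflicting class of pathogenicity",
      "Likely pathogenic", "Pathogenic/Likely pathogenic", "PATHOGENIC"
    )),
    c("benign", "likely_benign", "benign_likely_benign",
      "uncertain_significance", "conflicting", "conflicting",
      "likely_pathogenic", "pathogenic_likely_pathogenic", "pathogenic")
  )
  expect_error(normalize_category("drug response"), "unrecognized")
})

test_that("missense filtering respects compound annotations", {
  fixture <- tibble::tibble(
    consequence = c(
      rep("missense_variant", 4),
      "missense_variant|intron_variant",
      "missense_variant|splice_donor_variant",
      "intron_variant|missense_variant",
      "intron_variant", "synonymous_variant", "stop_gained"
    )
  )
  expect_equal(nrow(filter_missense(fixture, compound_ok = TRUE)), 7L)
  expect_equal(nrow(filter_missense(fixture, compound_ok = FALSE)), 4L)
  expect_error(filter_missense(tibble::tibble(x = 1)), "consequence")
})

test_that("merge_sources unions on the protein change with provenance", {
  set.seed(42)
  reference <- random_aa_seq(960)
  all_recs <- make_records(128, reference)

  clinvar <- all_recs[1:120, ]
  kgp <- dplyr::bind_rows(all_recs[117:120, ], all_recs[121:128, ])
  merged <- merge_sources(list(clinvar = clinvar, kgp = kgp))
  expect_equal(nrow(merged), 128L)
  expect_equal(sum(merged$sources == "clinvar,kgp"), 4L)
  expect_equal(sum(merged$sources == "kgp"), 8L)

  # idempotence: merging a set with itself changes nothing but provenance
  again <- merge_sources(list(clinvar = clinvar, clinvar2 = clinvar))
  expect_equal(nrow(again), 120L)
  expect_setequal(
    paste(again$ref, again$pos, again$alt),
    paste(clinvar$ref, clinvar$pos, clinvar$alt)
  )

  # three pairwise-disjoint sources of 120/8/30 union to 158
  three <- make_records(158, reference)
  merged3 <- merge_sources(list(clinvar = three[1:120, ],
                                kgp = three[121:128, ],
                                literature = three[129:158, ]))
  expect_equal(nrow(merged3), 158L)

  # commutativity on variant identity
  merged3_rev <- merge_sources(list(literature = three[129:158, ],
                                    kgp = three[121:128, ],
                                    clinvar = three[1:120, ]))
  expect_setequal(
    paste(merged3$ref, merged3$pos, merged3$alt),
    paste(merged3_rev$ref, merged3_rev$pos, merged3_rev$alt)
  )
})

test_that("category disagreements keep the ClinVar call and are logged", {
  reference <- paste(rep("A", 50), collapse = "")
  rec <- tibble::tibble(ref = "A", pos = 10L, alt = "V", missense = TRUE,
                        consequence = "missense_variant",
                        category = "benign", af = NA_real_)
  rec2 <- rec
  rec2$category <- "pathogenic"

  m1 <- merge_sources(list(kgp = rec2, clinvar = rec))
  expect_equal(m1$category, "benign")
  expect_equal(nrow(attr(m1, "conflicts")), 1L)

  m2 <- merge_sources(list(clinvar = rec, kgp = rec2))
  expect_equal(m2$category, "benign")
})

test_that("reference validation partitions records and reports reasons", {
  set.seed(7)
  reference <- random_aa_seq(960)
  good <- make_records(156, reference)
  bad <- good[1:2, ]
  bad$pos <- c(5L, 900L)
  truth_res <- substring(reference, bad$pos, bad$pos)
  bad$ref <- vapply(truth_res, function(r) setdiff(AA20, r)[1], character(1))
  bad$alt <- vapply(bad$ref, function(r) setdiff(AA20, r)[1], character(1))

  input <- dplyr::bind_rows(good, bad)
  out <- validate_against_reference(input, reference)
  expect_equal(nrow(out$kept), 156L)
  expect_equal(nrow(out$discarded), 2L)
  expect_true(all(out$discarded$reason == "ref_mismatch"))
  expect_equal(nrow(out$kept) + nrow(out$discarded), nrow(input))

  oob <- good[1, ]
  oob$pos <- 2000L
  res <- validate_against_reference(oob, reference)
  expect_equal(res$discarded$reason, "out_of_range")

  expect_error(validate_against_reference(good, ""), "empty")
})

test_that("region assignment uses inclusive 1-based intervals", {
  recs <- tibble::tibble(ref = c("L", "A", "T"), pos = c(302L, 303L, 170L),
                         alt = c("F", "V", "A"))
  ann <- assign_regions(recs)
  labels <- strsplit(ann$regions, ",")
  expect_true("kinase_domain" %in% labels[[1]])   # residue 302 is inside
  expect_false("kinase_domain" %in% labels[[2]])  # residue 303 is not
  expect_setequal(labels[[3]], c("kinase_domain", "tey_motif"))
})

test_that("category tallies are conserved under region partition", {
  kinase_counts <- cdkl5_category_counts("kinase")
  full_counts <- cdkl5_category_counts("full")
  expect_equal(sum(kinase_counts), 112L)
  expect_equal(sum(full_counts), 156L)

  vt <- generate_variant_table(generator_config(seed = 11, scope = "full"))
  tallies_all <- summarize_categories(vt$variants)
  expect_equal(tallies_all, full_counts)
  inside <- summarize_categories(vt$variants, region = "kinase_domain")
  expect_equal(inside, kinase_counts)

  # conservation: inside + outside = all, for every region
  for (region in c("kinase_domain", "tey_motif", "nes")) {
    ins <- summarize_categories(vt$variants, region = region)
    labs <- strsplit(vt$variants$regions, ",")
    outside <- vt$variants[!vapply(labs, function(x) region %in% x,
                                   logical(1)), ]
    outs <- summarize_categories(outside)
    expect_equal(ins + outs, tallies_all)
  }

  expect_error(summarize_categories(vt$variants, region = "nonesuch"),
               "unknown region")
  empty <- summarize_categories(vt$variants[0, ])
  expect_true(all(empty == 0L))
})

test_that("curated tables round-trip through TSV field-for-field", {
  vt <- generate_variant_table(generator_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curated_table(vt$variants, path)
  back <- read_curated_table(path)
  cols <- c("ref", "pos", "alt", "category", "sources", "regions", "af")
  expect_equal(as.data.frame(back[, cols]),
               as.data.frame(vt$variants[, cols]),
               ignore_attr = TRUE)
})
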