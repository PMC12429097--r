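# Synthetic-data generation: every input the pipeline consumes (curated
# variant tables, folding/binding ddG tables, substrate sequences, raw
# source exports) with the statistical structure the analysis assumes and
# a ground-truth record sufficient to score each stage exactly. A single
# root seed drives independent per-stage substreams so stages can be
# regenerated in isolation; fixed seed implies byte-identical output.

stage_seed <- function(config, stage) {
  offsets <- c(variants = 101L, ddg = 211L, sequences = 307L,
               exports = 401L)
  as.integer((as.numeric(config$seed) + offsets[[stage]]) %%
               .Machine$integer.max)
}

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions: per-category variant counts equal
#' to the published kinase-domain (or full-length) tallies, class-
#' conditional ddG means per method (and complex) from the published
#' summaries on each method's native sign convention, Gaussian noise of
#' 0.5 kcal/mol per method (dispersions are not published; this is a
#' package choice), an 85:15 serine:threonine phosphoacceptor ratio, and
#' for separable scenarios a planted cutoff with a 0.18 kcal/mol support
#' gap mirroring the observed 0.68 -> 0.86 training gap.
#'
#' @param seed Integer root seed.
#' @param scope `"kinase"` (variants within residues 1-302) or `"full"`
#'   (full-length tallies, kinase subset placed within 1-302).
#' @param category_counts Named counts over [germline_levels()].
#' @param kinase_counts Kinase-domain share of `category_counts` (used for
#'   `scope = "full"` placement).
#' @param protein_length Reference protein length (default 960).
#' @param kinase_end Last kinase-domain residue (default 302).
#' @param folding_class_means,binding_class_means Class-mean tables, see
#'   [folding_class_means()] / [binding_class_means()].
#' @param noise_sd Per-method Gaussian noise, kcal/mol.
#' @param ser_thr_ratio Length-2 numeric summing to 1: P(serine),
#'   P(threonine) for planted phosphoacceptors.
#' @param separable Rescale per-variant statistics so benign/pathogenic
#'   supports are disjoint around the planted thresholds?
#' @param planted_threshold Named list `ddg_fmax`/`ddg_bmax` of planted
#'   cutoffs for separable mode (defaults 0.77 and 0.885 kcal/mol).
#' @param gap Width of the empty support interval around a planted cutoff.
#' @return Object of class `generator_config` (a list).
#' @export
generator_config <- function(seed = 1L,
                             scope = c("kinase", "full"),
                             category_counts = NULL,
                             kinase_counts = cdkl5_category_counts("kinase"),
                             protein_length = 960L,
                             kinase_end = 302L,
                             folding_class_means =
                               cdkl5ddg::folding_class_means("structure"),
                             binding_class_means =
                               cdkl5ddg::binding_class_means(),
                             noise_sd = 0.5,
                             ser_thr_ratio = c(serine = 0.85,
                                               threonine = 0.15),
                             separable = FALSE,
                             planted_threshold = list(ddg_fmax = 0.77,
                                                      ddg_bmax = 0.885),
                             gap = 0.18) {
  scope <- match.arg(scope)
  if (is.null(category_counts)) {
    category_counts <- cdkl5_category_counts(scope)
  }
  stopifnot(
    all(category_counts >= 0),
    noise_sd >= 0,
    abs(sum(ser_thr_ratio) - 1) < 1e-8,
    gap > 0
  )
  structure(
    list(
      seed = as.integer(seed),
      scope = scope,
      category_counts = category_counts,
      kinase_counts = kinase_counts,
      protein_length = as.integer(protein_length),
      kinase_end = as.integer(kinase_end),
      folding_class_means = folding_class_means,
      binding_class_means = binding_class_means,
      noise_sd = noise_sd,
      ser_thr_ratio = ser_thr_ratio,
      separable = separable,
      planted_threshold = planted_threshold,
      gap = gap
    ),
    class = "generator_config"
  )
}

random_protein <- function(length) {
  paste(sample(AA_STANDARD, length, replace = TRUE), collapse = "")
}

# Draw n distinct protein changes with positions in [lo, hi], consistent
# with the reference sequence. `seen_env$seen` carries the identifiers
# already drawn so distinctness holds across categories and ranges.
sample_changes <- function(n, lo, hi, reference, seen_env = NULL) {
  if (n == 0) {
    return(tibble(ref = character(), pos = integer(), alt = character()))
  }
  if (is.null(seen_env)) {
    seen_env <- new.env()
    seen_env$seen <- character(0)
  }
  capacity <- (hi - lo + 1L) * (length(AA_STANDARD) - 1L)
  if (n + length(seen_env$seen) > capacity) {
    stop("requested ", n, " changes exceed the ", capacity,
         " available substitutions in positions ", lo, "-", hi,
         call. = FALSE)
  }
  out <- list()
  while (length(out) < n) {
    pos <- sample(lo:hi, 1L)
    ref <- substring(reference, pos, pos)
    alt <- sample(setdiff(AA_STANDARD, ref), 1L)
    key <- variant_id(ref, pos, alt)
    if (!key %in% seen_env$seen) {
      seen_env$seen <- c(seen_env$seen, key)
      out[[key]] <- tibble(ref = ref, pos = pos, alt = alt)
    }
  }
  dplyr::bind_rows(out)
}

#' Generate a curated-format variant table with ground truth
#'
#' Samples distinct protein changes consistent with a freshly generated
#' reference sequence, with exactly the configured number of variants per
#' germline category. Under `scope = "kinase"` all positions fall within
#' the kinase domain; under `scope = "full"` the configured kinase share
#' of each category is placed within the kinase domain and the remainder
#' beyond it. Deterministic under a fixed seed.
#'
#' @param config A [generator_config()].
#' @return List with `variants` (curated-format tibble), `truth` (tibble
#'   with `variant`, `category`, `true_class`, `pos`) and `reference`
#'   (protein sequence string).
#' @export
generate_variant_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(stage_seed(config, "variants"), {
    reference <- random_protein(config$protein_length)
    counts <- config$category_counts
    pieces <- list()
    seen_env <- new.env()
    seen_env$seen <- character(0)
    for (cat in names(counts)) {
      n_total <- counts[[cat]]
      if (n_total == 0) next
      if (config$scope == "kinase") {
        n_kin <- n_total
      } else {
        n_kin <- min(config$kinase_counts[[cat]], n_total)
      }
      n_cterm <- n_total - n_kin
      chg <- dplyr::bind_rows(
        sample_changes(n_kin, 1L, config$kinase_end, reference, seen_env),
        sample_changes(n_cterm, config$kinase_end + 1L,
                       config$protein_length, reference, seen_env)
      )
      chg$category <- cat
      pieces[[cat]] <- chg
    }
    variants <- dplyr::bind_rows(pieces)
    if (nrow(variants) == 0) {
      variants <- tibble(ref = character(), pos = integer(),
                         alt = character(), category = character())
    }
    variants$sources <- rep("synthetic", nrow(variants))
    variants$af <- rep(NA_real_, nrow(variants))
    variants <- assign_regions(variants)
    variants <- variants[order(variants$pos, variants$ref, variants$alt), ,
                         drop = FALSE]
    truth <- tibble(
      variant = variant_id(variants$ref, variants$pos, variants$alt),
      category = variants$category,
      true_class = ifelse(variants$category %in% benign_group(),
                          "benign", "pathogenic"),
      pos = variants$pos
    )
    list(variants = variants, truth = truth, reference = reference)
  })
}

class_mean_lookup <- function(means, class) {
  if (identical(class, "benign")) means$benign else means$pathogenic
}

# Rescale one variant's table values so its statistic hits `target`.
rescale_to_target <- function(values, current, target) {
  if (current <= 0) stop("cannot rescale a zero statistic", call. = FALSE)
  values * (target / current)
}

#' Generate folding and binding ddG tables for a variant set
#'
#' Each folding cell is drawn as Normal(class mean, noise_sd) on the
#' method's native sign convention; binding cells likewise per method and
#' complex. In separable mode the per-variant values are rescaled so the
#' resulting ddG_Fmax / ddG_Bmax supports are disjoint around the planted
#' thresholds: benign statistics fall at or below `threshold - gap/2`,
#' pathogenic at or above `threshold + gap/2`, and one strictly annotated
#' variant of each class is pinned to the corresponding support edge so
#' the derived midpoint reproduces the planted cutoff exactly.
#'
#' @param config A [generator_config()].
#' @param truth Truth tibble from [generate_variant_table()].
#' @return List with long tibbles `folding` (`variant`, `method`, `ddg`)
#'   and `binding` (`variant`, `method`, `complex`, `ddg`).
#' @export
generate_ddg_tables <- function(config, truth) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(stage_seed(config, "ddg"), {
    fm <- config$folding_class_means
    bm <- config$binding_class_means

    folding <- tidyr::crossing(variant = truth$variant, method = fm$method)
    folding <- dplyr::left_join(folding, truth[, c("variant", "true_class")],
                                by = "variant")
    fmean <- setNames(fm$pathogenic, fm$method)
    fmean_b <- setNames(fm$benign, fm$method)
    mu <- ifelse(folding$true_class == "benign",
                 fmean_b[folding$method], fmean[folding$method])
    folding$ddg <- rnorm(nrow(folding), mean = mu, sd = config$noise_sd)

    bkey <- paste(bm$method, bm$complex, sep = "|")
    binding <- tidyr::crossing(variant = truth$variant,
                               tibble(method = bm$method,
                                      complex = bm$complex))
    binding <- dplyr::left_join(binding, truth[, c("variant", "true_class")],
                                by = "variant")
    bmean_p <- setNames(bm$pathogenic, bkey)
    bmean_b <- setNames(bm$benign, bkey)
    key <- paste(binding$method, binding$complex, sep = "|")
    mu_b <- ifelse(binding$true_class == "benign",
                   bmean_b[key], bmean_p[key])
    binding$ddg <- rnorm(nrow(binding), mean = mu_b, sd = config$noise_sd)

    if (isTRUE(config$separable)) {
      folding <- plant_separable(folding, truth, "ddg_fmax",
                                 config$planted_threshold$ddg_fmax,
                                 config$gap)
      binding <- plant_separable(binding, truth, "ddg_bmax",
                                 config$planted_threshold$ddg_bmax,
                                 config$gap)
    }

    list(
      folding = folding[, c("variant", "method", "ddg")],
      binding = binding[, c("variant", "method", "complex", "ddg")]
    )
  })
}

# Rescale per-variant values so the class supports of the statistic are
# disjoint around `threshold`, pinning one strict benign and one strict
# pathogenic variant to the support edges.
plant_separable <- function(table, truth, statistic, threshold, gap) {
  half <- gap / 2
  lo_edge <- threshold - half
  hi_edge <- threshold + half

  strict <- split(
    truth$variant[truth$category %in% c("benign", "pathogenic")],
    truth$category[truth$category %in% c("benign", "pathogenic")]
  )
  pin_benign <- if (length(strict$benign)) strict$benign[1] else NA
  pin_path <- if (length(strict$pathogenic)) strict$pathogenic[1] else NA

  classes <- setNames(truth$true_class, truth$variant)
  pieces <- lapply(split(table, table$variant), function(slice) {
    v <- slice$variant[1]
    current <- if (statistic == "ddg_fmax") {
      ddg_fmax(setNames(slice$ddg, slice$method))$value
    } else {
      ddg_bmax(slice)$value
    }
    target <- if (identical(v, pin_benign)) {
      lo_edge
    } else if (identical(v, pin_path)) {
      hi_edge
    } else if (classes[[v]] == "benign") {
      runif(1, max(0.05, lo_edge - 0.6), lo_edge)
    } else {
      runif(1, hi_edge, hi_edge + 1.5)
    }
    if (current <= 0) {
      # degenerate all-zero draw: seed one cell so rescaling is defined
      slice$ddg[1] <- 0.1
      current <- 0.1
    }
    slice$ddg <- rescale_to_target(slice$ddg, current, target)
    slice
  })
  out <- dplyr::bind_rows(pieces)
  out[order(match(out$variant, unique(table$variant))), , drop = FALSE]
}

#' Generate substrate sequences with planted consensus motifs
#'
#' Backgrounds are drawn uniformly over the 20 standard residues and
#' rejected until motif-free under [scan_consensus()]; each planted motif
#' draws its phosphoacceptor S/T at the configured ratio. Sequences are
#' re-drawn until the scanner finds exactly the planted sites, so recall
#' is 1 by construction and no spurious site survives.
#'
#' @param config A [generator_config()].
#' @param n_sequences Number of sequences.
#' @param seq_length Sequence length.
#' @param sites_per_seq Motifs planted per sequence.
#' @param spec Motif specification.
#' @return List with `sequences` (named character vector) and `truth`
#'   (tibble `seq_id`, `pos`, `residue`).
#' @export
generate_sequences <- function(config, n_sequences = 100, seq_length = 200,
                               sites_per_seq = 1, spec = motif_spec()) {
  stopifnot(inherits(config, "generator_config"))
  k <- length(spec$classes)
  if (sites_per_seq * (2 * k) > seq_length) {
    stop("requested motif density is infeasible for this sequence length",
         call. = FALSE)
  }
  withr::with_seed(stage_seed(config, "sequences"), {
    truth <- list()
    seqs <- character(n_sequences)
    for (i in seq_len(n_sequences)) {
      repeat {
        s <- random_protein(seq_length)
        if (nrow(scan_consensus(s, spec)) > 0) next
        # non-overlapping plant positions
        slots <- sort(as.integer(sample(seq(1L, seq_length - k + 1L,
                                            by = k), sites_per_seq)))
        planted <- integer(0)
        residues <- character(0)
        for (start in slots) {
          motif <- vapply(spec$classes, function(cls) sample(cls, 1L),
                          character(1))
          acceptor <- sample(c("S", "T"), 1L,
                             prob = config$ser_thr_ratio)
          motif[spec$phospho_slot] <- acceptor
          substr(s, start, start + k - 1L) <- paste(motif, collapse = "")
          planted <- c(planted, start + spec$phospho_slot - 1L)
          residues <- c(residues, acceptor)
        }
        hits <- scan_consensus(s, spec)
        if (nrow(hits) == length(planted) &&
            identical(sort(hits$pos), sort(planted))) {
          seqs[i] <- s
          truth[[i]] <- tibble(seq_id = paste0("synthetic_", i),
                               pos = planted, residue = residues)
          break
        }
      }
    }
    names(seqs) <- paste0("synthetic_", seq_len(n_sequences))
    list(sequences = seqs, truth = dplyr::bind_rows(truth))
  })
}

category_display <- function(category) {
  display <- c(
    benign = "Benign",
    likely_benign = "Likely benign",
    benign_likely_benign = "Benign/Likely benign",
    uncertain_significance = "Uncertain significance",
    conflicting = "Conflicting classifications of pathogenicity",
    likely_pathogenic = "Likely pathogenic",
    pathogenic_likely_pathogenic = "Pathogenic/Likely pathogenic",
    pathogenic = "Pathogenic"
  )
  unname(display[category])
}

#' Generate raw source exports with planted curation artefacts
#'
#' Builds ClinVar-like, population-panel-like and literature-like TSV
#' record sets over a full-length synthetic variant set, with planted
#' cross-source overlaps, a within-source duplicate, non-missense
#' consequence rows, and exactly `n_mismatches` reference-mismatch
#' records, so that running [curate_variants()] on them reproduces the
#' planted counts (by default 120 + 12-with-4-overlaps + 30 sources,
#' 158 merged, 2 discarded, 156 curated).
#'
#' @param config A [generator_config()] (its `scope`/counts are overridden
#'   with the full-length tallies).
#' @param clinvar_n,kgp_unique,kgp_overlap,literature_n Source sizes.
#' @param n_mismatches Reference mismatches planted (split between the
#'   ClinVar-like and literature sources).
#' @return List with raw-record tibbles `clinvar`, `kgp`, `literature`
#'   (columns `variant`, `consequence`, `classification`, `af`),
#'   `reference` (sequence string) and `truth`.
#' @export
generate_source_exports <- function(config,
                                    clinvar_n = 120L,
                                    kgp_unique = 8L,
                                    kgp_overlap = 4L,
                                    literature_n = 30L,
                                    n_mismatches = 2L) {
  stopifnot(inherits(config, "generator_config"))
  n_good <- clinvar_n + kgp_unique + literature_n - n_mismatches
  full_counts <- cdkl5_category_counts("full")
  total_full <- sum(full_counts)
  if (n_good != total_full) {
    # scale the full-length tallies to the requested total, preserving the
    # category mix as closely as possible
    scaled <- round(full_counts * n_good / total_full)
    diff <- n_good - sum(scaled)
    scaled[which.max(scaled)] <- scaled[which.max(scaled)] + diff
    full_counts <- scaled
  }
  cfg <- generator_config(
    seed = config$seed, scope = "full", category_counts = full_counts,
    kinase_counts = pmin(cdkl5_category_counts("kinase"), full_counts),
    protein_length = config$protein_length, kinase_end = config$kinase_end,
    noise_sd = config$noise_sd, ser_thr_ratio = config$ser_thr_ratio
  )
  vt <- generate_variant_table(cfg)

  withr::with_seed(stage_seed(config, "exports"), {
    good <- vt$truth
    good$af <- ifelse(runif(nrow(good)) < 0.3,
                      signif(runif(nrow(good), 1e-6, 1e-3), 3), NA_real_)

    idx <- sample(nrow(good))
    clinvar_good <- good[idx[seq_len(clinvar_n - ceiling(n_mismatches / 2))], ]
    kgp_rows <- good[idx[(clinvar_n - ceiling(n_mismatches / 2) + 1):
                           (clinvar_n - ceiling(n_mismatches / 2) +
                              kgp_unique)], ]
    lit_good <- good[idx[(clinvar_n - ceiling(n_mismatches / 2) +
                            kgp_unique + 1):nrow(good)], ]

    # reference-mismatch records: wild-type letter deliberately wrong
    bad <- list()
    taken <- good$variant
    while (length(bad) < n_mismatches) {
      pos <- sample(config$protein_length, 1L)
      true_ref <- substring(vt$reference, pos, pos)
      ref <- sample(setdiff(AA_STANDARD, true_ref), 1L)
      alt <- sample(setdiff(AA_STANDARD, ref), 1L)
      id <- variant_id(ref, pos, alt)
      if (!id %in% taken) {
        taken <- c(taken, id)
        bad[[id]] <- tibble(variant = id,
                            category = "uncertain_significance",
                            af = NA_real_)
      }
    }
    bad <- dplyr::bind_rows(bad)
    bad_clinvar <- bad[seq_len(ceiling(n_mismatches / 2)), , drop = FALSE]
    bad_lit <- bad[setdiff(seq_len(n_mismatches),
                           seq_len(ceiling(n_mismatches / 2))), ,
                   drop = FALSE]

    overlap <- clinvar_good[sample(nrow(clinvar_good), kgp_overlap), ]

    as_export <- function(tab) {
      n <- nrow(tab)
      consequence <- sample(c("missense_variant",
                              "missense_variant|intron_variant"),
                            n, replace = TRUE, prob = c(0.8, 0.2))
      tibble(
        variant = tab$variant,
        consequence = consequence,
        classification = category_display(tab$category),
        af = if ("af" %in% names(tab)) tab$af else NA_real_
      )
    }

    clinvar <- dplyr::bind_rows(as_export(clinvar_good),
                                as_export(bad_clinvar))
    # planted within-source duplicate: removed by per-source dedup
    clinvar <- dplyr::bind_rows(clinvar, clinvar[1, ])
    # planted non-missense rows: dropped by the consequence filter
    noise_tokens <- c("A901T", "G902S")
    clinvar <- dplyr::bind_rows(
      clinvar,
      tibble(variant = noise_tokens,
             consequence = c("intron_variant", "synonymous_variant"),
             classification = "Uncertain significance",
             af = NA_real_)
    )
    kgp <- dplyr::bind_rows(as_export(kgp_rows), as_export(overlap))
    literature <- dplyr::bind_rows(as_export(lit_good), as_export(bad_lit))

    list(
      clinvar = clinvar,
      kgp = kgp,
      literature = literature,
      reference = vt$reference,
      truth = list(
        variants = vt$truth,
        mismatch_ids = bad$variant,
        overlap_ids = overlap$variant,
        duplicate_id = clinvar$variant[1]
      )
    )
  })
}

#' Write synthetic source exports to a directory
#'
#' Emits `clinvar.tsv`, `kgp.tsv`, `literature.tsv` and `reference.fasta`.
#'
#' @param exports Result of [generate_source_exports()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_source_exports <- function(exports, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(exports$clinvar, file.path(dir, "clinvar.tsv"),
                   progress = FALSE)
  readr::write_tsv(exports$kgp, file.path(dir, "kgp.tsv"), progress = FALSE)
  readr::write_tsv(exports$literature, file.path(dir, "literature.tsv"),
                   progress = FALSE)
  ref <- Biostrings::AAStringSet(setNames(exports$reference, "reference"))
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"))
  invisible(dir)
}
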