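# Curation of missense-variant records: consequence filtering, cross-source
# merging with provenance, reference validation, region annotation and
# category bookkeeping.

#' Read a tab-separated variant source export
#'
#' Expects a header row with at least `variant`, `consequence` and
#' `classification` columns (`condition` and `af` optional). Variant tokens
#' are parsed with [parse_protein_change()] and classifications harmonized
#' with [normalize_category()].
#'
#' @param path Path to a TSV export.
#' @return A raw-record tibble with columns `ref`, `pos`, `alt`, `missense`,
#'   `consequence`, `category`, `af`.
#' @export
read_source_export <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("variant", "consequence", "classification")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("source export ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_protein_change(raw$variant)
  tibble(
    ref = parsed$ref,
    pos = parsed$pos,
    alt = parsed$alt,
    missense = parsed$missense,
    consequence = as.character(raw$consequence),
    category = normalize_category(raw$classification),
    af = if ("af" %in% names(raw)) as.numeric(raw$af) else NA_real_
  )
}

#' Filter rows to missense consequences
#'
#' Keeps rows whose `consequence` annotation contains the term
#' `missense_variant` among its `|`-separated terms. With
#' `compound_ok = FALSE` only pure `missense_variant` rows (a single term)
#' are retained, dropping compound annotations such as
#' `missense_variant|intron_variant`.
#'
#' @param records Tibble with a `consequence` column.
#' @param compound_ok Keep compound missense annotations? Default `TRUE`.
#' @return The retained rows.
#' @export
filter_missense <- function(records, compound_ok = TRUE) {
  if (!"consequence" %in% names(records)) {
    stop("records lack a 'consequence' column", call. = FALSE)
  }
  terms <- strsplit(as.character(records$consequence), "|", fixed = TRUE)
  has_missense <- purrr::map_lgl(terms, ~ "missense_variant" %in% .x)
  keep <- if (compound_ok) {
    has_missense
  } else {
    has_missense & lengths(terms) == 1L
  }
  records[keep, , drop = FALSE]
}

dedup_within_source <- function(records, source) {
  key <- variant_id(records$ref, records$pos, records$alt)
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate record(s) removed within source '",
            source, "'")
  }
  records[!dup, , drop = FALSE]
}

#' Merge variant records from multiple sources
#'
#' Takes a named list of per-source record tibbles (names become provenance
#' labels, e.g. `clinvar`, `kgp`, `literature`), deduplicates each source on
#' the protein-level change, and unions them keyed on (`ref`, `pos`, `alt`).
#' Overlapping records merge their provenance sets. When sources disagree on
#' the germline category, the ClinVar-sourced category wins if present,
#' otherwise the first-seen category; all disagreements are recorded in the
#' `conflicts` attribute of the result (a tibble with the variant and the
#' competing categories), never raised as errors.
#'
#' @param source_sets Named list of record tibbles with columns `ref`,
#'   `pos`, `alt`, `category` (and optionally `af`, `consequence`).
#' @param clinvar_name Source name treated as the clinical authority for
#'   category disagreements. Default `"clinvar"`.
#' @return A merged tibble with a comma-joined `sources` column, carrying a
#'   `conflicts` attribute.
#' @export
merge_sources <- function(source_sets, clinvar_name = "clinvar") {
  stopifnot(is.list(source_sets), !is.null(names(source_sets)))
  merged <- list()
  conflicts <- list()

  for (src in names(source_sets)) {
    recs <- dedup_within_source(source_sets[[src]], src)
    if (nrow(recs) == 0) next
    for (i in seq_len(nrow(recs))) {
      rec <- recs[i, , drop = FALSE]
      key <- variant_id(rec$ref, rec$pos, rec$alt)
      if (is.null(merged[[key]])) {
        rec$sources <- src
        merged[[key]] <- rec
      } else {
        prev <- merged[[key]]
        srcs <- union(strsplit(prev$sources, ",")[[1]], src)
        if (!identical(prev$category, rec$category)) {
          # ClinVar is the clinical authority: its category displaces a
          # previously seen one from another source; otherwise first-seen
          # wins. Either way the disagreement is logged.
          if (identical(src, clinvar_name)) {
            kept_cat <- rec$category
            disc_cat <- prev$category
            prev$category <- rec$category
          } else {
            kept_cat <- prev$category
            disc_cat <- rec$category
          }
          conflicts[[length(conflicts) + 1L]] <- tibble(
            variant = key,
            kept = kept_cat,
            discarded = disc_cat,
            source = src
          )
        }
        if (is.na(prev$af) && !is.null(rec$af) && !is.na(rec$af)) {
          prev$af <- rec$af
        }
        prev$sources <- paste(sort(srcs), collapse = ",")
        merged[[key]] <- prev
      }
    }
  }

  out <- dplyr::bind_rows(merged)
  if (nrow(out) == 0) {
    out <- tibble(ref = character(), pos = integer(), alt = character(),
                  category = character(), af = numeric(),
                  sources = character())
  }
  attr(out, "conflicts") <- dplyr::bind_rows(conflicts)
  out
}

#' Validate variant records against the reference protein sequence
#'
#' A record is kept iff its position lies within the reference sequence and
#' the reference residue at that (1-based) position equals the record's
#' wild-type residue. Discarded records are returned alongside, with a
#' `reason` column (`ref_mismatch` or `out_of_range`).
#'
#' @param records Record tibble with `ref` and `pos` columns.
#' @param reference_sequence Protein sequence as a single string or a
#'   `Biostrings::AAString`.
#' @return A list with elements `kept` and `discarded`.
#' @export
validate_against_reference <- function(records, reference_sequence) {
  seq <- toupper(as.character(reference_sequence))
  if (!nzchar(seq)) stop("reference sequence is empty", call. = FALSE)
  n <- nchar(seq)
  in_range <- records$pos >= 1L & records$pos <= n
  observed <- rep(NA_character_, nrow(records))
  if (any(in_range)) {
    observed[in_range] <- substring(seq, records$pos[in_range],
                                    records$pos[in_range])
  }
  match <- in_range & !is.na(observed) & observed == records$ref

  discarded <- records[!match, , drop = FALSE]
  if (nrow(discarded) > 0) {
    discarded$reason <- ifelse(in_range[!match], "ref_mismatch",
                               "out_of_range")
  } else {
    discarded$reason <- character(0)
  }
  list(kept = records[match, , drop = FALSE], discarded = discarded)
}

#' Annotate records with protein-region labels
#'
#' Adds a `regions` column: the comma-joined names of every region whose
#' inclusive 1-based interval contains the variant position.
#'
#' @param records Record tibble with a `pos` column.
#' @param regions Region tibble as from [cdkl5_regions()].
#' @return `records` with a `regions` column.
#' @export
assign_regions <- function(records, regions = cdkl5_regions()) {
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  if (any(regions$start > regions$end) || any(regions$start < 1L)) {
    stop("invalid region intervals", call. = FALSE)
  }
  records$regions <- purrr::map_chr(records$pos, function(p) {
    hit <- regions$name[regions$start <= p & p <= regions$end]
    paste(hit, collapse = ",")
  })
  records
}

#' Tally records per germline category
#'
#' Counts curated records per canonical category, optionally restricted to
#' records annotated with a given region label. All eight categories are
#' reported, with zero counts where empty.
#'
#' @param records Curated record tibble with `category` (and `regions` when
#'   filtering).
#' @param region Optional region name to filter on.
#' @param regions Region universe used to validate `region`.
#' @return Named integer vector over [germline_levels()].
#' @export
summarize_categories <- function(records, region = NULL,
                                 regions = cdkl5_regions()) {
  if (!is.null(region)) {
    if (!region %in% regions$name) {
      stop("unknown region name: ", region, call. = FALSE)
    }
    labels <- strsplit(records$regions, ",", fixed = TRUE)
    records <- records[purrr::map_lgl(labels, ~ region %in% .x), ,
                       drop = FALSE]
  }
  cat <- factor(records$category, levels = GERMLINE_LEVELS)
  counts <- table(cat)
  setNames(as.integer(counts), GERMLINE_LEVELS)
}

#' Run the full curation pipeline on source exports
#'
#' Filters each source to missense consequences, deduplicates and merges
#' with provenance, validates against the reference protein sequence, and
#' annotates regions. This is the programmatic equivalent of the curated
#' 156-variant table construction: merge (158 records) -> discard reference
#' mismatches (2) -> annotate.
#'
#' @param sources Named list of raw record tibbles (see
#'   [read_source_export()]).
#' @param reference Reference protein sequence (string or `AAString`).
#' @param regions Region annotation set.
#' @param compound_ok Passed to [filter_missense()].
#' @return A list with `variants` (curated tibble), `discarded` (discard
#'   report) and `conflicts` (category disagreements).
#' @export
curate_variants <- function(sources, reference, regions = cdkl5_regions(),
                            compound_ok = TRUE) {
  filtered <- purrr::map(sources, filter_missense, compound_ok = compound_ok)
  filtered <- purrr::map(filtered, function(x) {
    x[x$missense %||% TRUE, , drop = FALSE]
  })
  merged <- merge_sources(filtered)
  validated <- validate_against_reference(merged, reference)
  curated <- assign_regions(validated$kept, regions)
  curated <- curated[order(curated$pos, curated$ref, curated$alt), ,
                     drop = FALSE]
  list(
    variants = curated,
    discarded = validated$discarded,
    conflicts = attr(merged, "conflicts")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read a curated variant table
#'
#' The on-disk format is TSV with columns `ref`, `pos`, `alt`, `category`,
#' `sources`, `regions`, `af`; a round trip reproduces the table
#' field-for-field.
#'
#' @param variants Curated tibble.
#' @param path Output/input path.
#' @return `write_curated_table()` returns `path` invisibly;
#'   `read_curated_table()` returns the tibble.
#' @export
write_curated_table <- function(variants, path) {
  cols <- c("ref", "pos", "alt", "category", "sources", "regions", "af")
  present <- intersect(cols, names(variants))
  readr::write_tsv(variants[, present, drop = FALSE], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_curated_table
#' @export
read_curated_table <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      ref = readr::col_character(),
      pos = readr::col_integer(),
      alt = readr::col_character(),
      category = readr::col_character(),
      sources = readr::col_character(),
      regions = readr::col_character(),
      af = readr::col_double()
    ),
    progress = FALSE
  )
  # an empty region set is written as an empty field; restore it
  if ("regions" %in% names(out)) {
    out$regions[is.na(out$regions)] <- ""
  }
  out
}
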