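# Midpoint-threshold classification: derive a cutoff from strictly
# annotated benign/pathogenic variants as the midpoint between the largest
# benign and smallest pathogenic statistic, call every variant against it,
# report how the original germline categories redistribute, and partition
# pathogenic variants by dominant thermodynamic mechanism.

#' Derive a midpoint threshold from strictly annotated variants
#'
#' Training labels must be strict (`"benign"` / `"pathogenic"` only; the
#' intermediate and ambiguous categories are not admissible training
#' labels). The threshold is the midpoint between the largest benign and
#' smallest pathogenic value of the statistic. When the training classes
#' overlap (`max_benign >= min_pathogenic`) the model is flagged
#' non-separable and cannot be used for classification.
#'
#' @param values Named numeric vector of per-variant statistic values
#'   (kcal/mol); names are variant ids.
#' @param labels Named character vector (or vector aligned with `values`)
#'   of strict training labels.
#' @param statistic Which statistic the values are: `"ddg_fmax"` or
#'   `"ddg_bmax"`.
#' @return An object of class `threshold_model`: list with `statistic`,
#'   `max_benign`, `min_pathogenic`, `midpoint`, `training_ids`,
#'   `separable`.
#' @export
#' @examples
#' derive_threshold(c(a = 0.68, b = 0.09, c = 0.86, d = 3.42),
#'                  c(a = "benign", b = "benign",
#'                    c = "pathogenic", d = "pathogenic"))$midpoint  # 0.77
derive_threshold <- function(values, labels,
                             statistic = c("ddg_fmax", "ddg_bmax")) {
  statistic <- match.arg(statistic)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("benign", "pathogenic"))
  if (length(bad) > 0) {
    stop("non-strict training label(s): ", paste(bad, collapse = ", "),
         "; only 'benign' and 'pathogenic' variants may train a threshold",
         call. = FALSE)
  }
  if (length(values) != length(labels)) {
    stop("values and labels differ in length", call. = FALSE)
  }
  if (any(is.na(values))) stop("missing training values", call. = FALSE)
  benign <- values[labels == "benign"]
  pathogenic <- values[labels == "pathogenic"]
  if (length(benign) == 0 || length(pathogenic) == 0) {
    stop("both a benign and a pathogenic training value are required",
         call. = FALSE)
  }
  max_benign <- max(benign)
  min_pathogenic <- min(pathogenic)
  structure(
    list(
      statistic = statistic,
      max_benign = max_benign,
      min_pathogenic = min_pathogenic,
      midpoint = (max_benign + min_pathogenic) / 2,
      training_ids = names(values) %||% rep(NA_character_, length(values)),
      separable = max_benign < min_pathogenic
    ),
    class = "threshold_model"
  )
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("<threshold_model> statistic:", x$statistic, "\n")
  cat("  benign max:     ", format(x$max_benign), "kcal/mol\n")
  cat("  pathogenic min: ", format(x$min_pathogenic), "kcal/mol\n")
  cat("  midpoint:        ", format(x$midpoint), " kcal/mol (displayed ",
      format(threshold_display(x), nsmall = 2), ")\n", sep = "")
  cat("  separable:      ", x$separable, " (", length(x$training_ids),
      " training variants)\n", sep = "")
  invisible(x)
}

#' Display value of a threshold
#'
#' Thresholds are reported truncated toward zero at two decimals (so a
#' midpoint of 0.885 displays as 0.88); classification always uses the
#' full-precision midpoint.
#'
#' @param model A `threshold_model` (or a bare numeric midpoint).
#' @param digits Decimal places kept. Default 2.
#' @return Numeric display value.
#' @export
threshold_display <- function(model, digits = 2L) {
  mid <- if (inherits(model, "threshold_model")) model$midpoint else model
  trunc(mid * 10^digits) / 10^digits
}

#' Classify statistic values against a threshold model
#'
#' Values strictly above the midpoint are called pathogenic; values at or
#' below it are called benign (the boundary rule is conservative, yielding
#' fewer pathogenic calls). Requires a separable model; missing values are
#' an error (use [reclassify_variants()] for `unclassified` handling).
#'
#' @param values Numeric vector of statistic values.
#' @param model A separable `threshold_model`.
#' @return Character vector of `"benign"` / `"pathogenic"` calls.
#' @export
classify <- function(values, model) {
  stopifnot(inherits(model, "threshold_model"))
  if (!model$separable) {
    stop("threshold model is not separable; no classification performed",
         call. = FALSE)
  }
  if (any(is.na(values))) {
    stop("missing statistic value(s); cannot classify", call. = FALSE)
  }
  ifelse(values > model$midpoint, "pathogenic", "benign")
}

#' Redistribution of original categories over new calls
#'
#' Cross-tabulates the original germline category of every variant against
#' its new binary call. Row marginals equal the original per-category
#' counts by construction. When `values` is supplied, the per-call value
#' ranges are attached as the `ranges` attribute.
#'
#' @param original Named character vector: variant -> original category.
#' @param calls Named character vector: variant -> new call (`"benign"`,
#'   `"pathogenic"`, possibly `"unclassified"`). Must cover every variant
#'   in `original`; variants in `calls` but not `original` are an error.
#' @param values Optional named numeric vector of the classified statistic.
#' @return Tibble with `category` plus one count column per call level.
#' @export
redistribute <- function(original, calls, values = NULL) {
  extra <- setdiff(names(calls), names(original))
  if (length(extra) > 0) {
    stop("variant(s) present in calls but not in original: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(names(original), names(calls))
  if (length(uncovered) > 0) {
    stop("calls do not cover variant(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  if (length(original) == 0) {
    return(tibble(category = character(), benign = integer(),
                  pathogenic = integer()))
  }
  call_levels <- union(c("benign", "pathogenic"), unique(calls))
  cat_levels <- c(intersect(GERMLINE_LEVELS, unique(original)),
                  setdiff(unique(original), GERMLINE_LEVELS))
  tab <- table(
    factor(original, levels = cat_levels),
    factor(calls[names(original)], levels = call_levels)
  )
  out <- as_tibble(as.data.frame.matrix(tab), rownames = "category")
  if (!is.null(values)) {
    rng <- lapply(split(values[names(calls)], calls), range, na.rm = TRUE)
    attr(out, "ranges") <- rng
  }
  out
}

#' Reclassify curated variants with a thermodynamic statistic
#'
#' End-to-end reclassification: picks the strictly annotated training
#' variants (original category exactly `benign` or `pathogenic`) from the
#' curated table, derives the midpoint threshold on the chosen statistic,
#' calls every variant with a present statistic value, marks variants
#' lacking the statistic `unclassified`, and tabulates the redistribution.
#' Each call carries a free-text computational-evidence tag (supporting
#' benign/pathogenic computational evidence) rather than a full ACMG/AMP
#' rule combination.
#'
#' @param aggregates Aggregate tibble from [aggregate_ddg()].
#' @param variants Curated variant tibble (columns `ref`, `pos`, `alt`,
#'   `category`).
#' @param statistic `"ddg_fmax"` or `"ddg_bmax"`.
#' @return List with `calls` (tibble: `variant`, `original_category`,
#'   `new_call`, `statistic`, `value`, `threshold`, `evidence`), `model`
#'   and `redistribution`.
#' @export
reclassify_variants <- function(aggregates, variants,
                                statistic = c("ddg_fmax", "ddg_bmax")) {
  statistic <- match.arg(statistic)
  ids <- variant_id(variants$ref, variants$pos, variants$alt)
  stat <- setNames(aggregates[[statistic]], aggregates$variant)[ids]
  categories <- setNames(variants$category, ids)

  strict <- categories %in% c("benign", "pathogenic") & !is.na(stat)
  model <- derive_threshold(stat[strict], categories[strict], statistic)

  calls <- rep("unclassified", length(ids))
  names(calls) <- ids
  has_stat <- !is.na(stat)
  calls[has_stat] <- classify(stat[has_stat], model)

  evidence <- dplyr::case_when(
    calls == "unclassified" ~ "no computational evidence (statistic absent)",
    calls == "pathogenic" ~ paste0("supporting pathogenic computational ",
                                   "evidence (", statistic, " above ",
                                   "midpoint threshold)"),
    TRUE ~ paste0("supporting benign computational evidence (", statistic,
                  " at or below midpoint threshold)")
  )

  list(
    calls = tibble(
      variant = ids,
      original_category = unname(categories),
      new_call = unname(calls),
      statistic = statistic,
      value = unname(stat),
      threshold = model$midpoint,
      evidence = evidence
    ),
    model = model,
    redistribution = redistribute(categories, calls, values = stat)
  )
}

#' Partition pathogenic variants by dominant thermodynamic mechanism
#'
#' Splits variants into folding-dominant (`ddg_fmax > ddg_bmax`;
#' candidates for stability-enhancing therapeutics) and binding-dominant
#' (`ddg_fmax <= ddg_bmax`; boundary equality counts as binding-dominant,
#' candidates for binding-restoring therapeutics). Both statistics must be
#' present for every variant. Outputs are sorted by residue position.
#'
#' @param aggregates Aggregate tibble (`variant`, `ddg_fmax`, `ddg_bmax`),
#'   typically restricted to pathogenic calls.
#' @return List with tibbles `folding_dominant` and `binding_dominant`.
#' @export
partition_mechanism <- function(aggregates) {
  if (any(is.na(aggregates$ddg_fmax)) || any(is.na(aggregates$ddg_bmax))) {
    stop("both statistics must be present for every variant", call. = FALSE)
  }
  pos <- parse_protein_change(aggregates$variant)$pos
  ord <- order(pos, aggregates$variant)
  aggregates <- aggregates[ord, , drop = FALSE]
  folding <- aggregates$ddg_fmax > aggregates$ddg_bmax
  list(
    folding_dominant = aggregates[folding, , drop = FALSE],
    binding_dominant = aggregates[!folding, , drop = FALSE]
  )
}
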