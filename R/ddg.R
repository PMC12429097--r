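# Harmonization and aggregation of multi-method ddG prediction tables into
# the per-variant statistics ddG_Fmax (maximum |ddG_folding| across methods)
# and ddG_Bmax (maximum over partner complexes of the method-averaged
# |ddG_binding|). Both statistics are sign-blind, which makes the
# predictors' conflicting sign conventions harmless for classification;
# sign canonicalization matters only for signed class summaries.

#' Canonicalize ddG values onto the mutant-minus-wildtype scale
#'
#' Values reported under the `wildtype_minus_mutant` convention are
#' negated; `mutant_minus_wildtype` values pass through unchanged.
#'
#' @param value Numeric vector of ddG values (kcal/mol).
#' @param sign_convention Either a convention string (recycled) or a
#'   character vector matching `value`.
#' @return Numeric vector on the mutant-minus-wildtype scale.
#' @export
#' @examples
#' canonicalize_sign(-0.91, "wildtype_minus_mutant")  # 0.91
canonicalize_sign <- function(value, sign_convention) {
  sign_convention <- rep_len(as.character(sign_convention), length(value))
  ok <- sign_convention %in% c("mutant_minus_wildtype",
                               "wildtype_minus_mutant")
  if (!all(ok)) {
    stop("unknown sign convention: ",
         paste(unique(sign_convention[!ok]), collapse = ", "),
         call. = FALSE)
  }
  ifelse(sign_convention == "wildtype_minus_mutant", -value, value)
}

#' Per-variant maximum absolute folding ddG
#'
#' `ddg_fmax()` takes one variant's per-method folding ddG values and
#' returns the maximum absolute value together with the contributing
#' method. Missing values are excluded; ties are broken by method-name
#' order.
#'
#' @param values Numeric vector of folding ddG values (kcal/mol), named by
#'   method (names optional).
#' @return List with elements `value` (kcal/mol, >= 0) and `method`.
#' @export
#' @examples
#' ddg_fmax(c(`I-Mutant2.0` = -1.2, mCSM = 0.5, DDGun = 0))$value  # 1.2
ddg_fmax <- function(values) {
  methods <- names(values) %||% paste0("method", seq_along(values))
  keep <- !is.na(values)
  if (!any(keep)) stop("all folding ddG values are missing", call. = FALSE)
  values <- values[keep]
  methods <- methods[keep]
  a <- abs(values)
  best <- a == max(a)
  winner <- sort(methods[best])[1]
  list(value = max(a), method = winner)
}

#' Per-variant maximum complex-average absolute binding ddG
#'
#' `ddg_bmax()` takes one variant's slice of a binding table (one row per
#' method x complex observation), averages `|ddG|` over the methods present
#' within each complex, and returns the maximum of those complex averages
#' with the contributing complex. Ties are broken by complex-name order.
#'
#' @param slice Tibble with columns `complex` and `ddg` (and anything
#'   else, ignored).
#' @return List with elements `value` (kcal/mol, >= 0) and `complex`.
#' @export
ddg_bmax <- function(slice) {
  slice <- slice[!is.na(slice$ddg), , drop = FALSE]
  if (nrow(slice) == 0) {
    stop("no binding ddG values present for this variant", call. = FALSE)
  }
  means <- tapply(abs(slice$ddg), slice$complex, mean)
  best <- means == max(means)
  winner <- sort(names(means)[best])[1]
  list(value = unname(max(means)), complex = winner)
}

#' Aggregate folding and binding tables into per-variant statistics
#'
#' Computes ddG_Fmax and ddG_Bmax for every variant present in the long
#' folding table (`variant`, `method`, `ddg`) and/or the binding table
#' (`variant`, `method`, `complex`, `ddg`). Variants lacking one table
#' entirely get `NA` for that statistic (they are reported, never silently
#' dropped); variants with no finite value at all in a table they appear in
#' are likewise `NA` with a warning.
#'
#' @param folding Long folding tibble, or `NULL`.
#' @param binding Long binding tibble, or `NULL`.
#' @param methods Optional character vector restricting the folding methods
#'   used (e.g. the five structure-based predictors).
#' @return Tibble with columns `variant`, `ddg_fmax`, `fmax_method`,
#'   `ddg_bmax`, `bmax_complex`.
#' @export
aggregate_ddg <- function(folding = NULL, binding = NULL, methods = NULL) {
  variants <- unique(c(
    if (!is.null(folding)) folding$variant,
    if (!is.null(binding)) binding$variant
  ))
  if (length(variants) == 0) {
    return(tibble(variant = character(), ddg_fmax = numeric(),
                  fmax_method = character(), ddg_bmax = numeric(),
                  bmax_complex = character()))
  }
  if (!is.null(folding) && !is.null(methods)) {
    folding <- folding[folding$method %in% methods, , drop = FALSE]
  }

  rows <- purrr::map(variants, function(v) {
    fm <- list(value = NA_real_, method = NA_character_)
    bm <- list(value = NA_real_, complex = NA_character_)
    if (!is.null(folding)) {
      f <- folding[folding$variant == v, , drop = FALSE]
      if (nrow(f) > 0 && any(!is.na(f$ddg))) {
        fm <- ddg_fmax(setNames(f$ddg, f$method))
      } else if (nrow(f) > 0) {
        warning("variant ", v, " has no usable folding ddG value",
                call. = FALSE)
      }
    }
    if (!is.null(binding)) {
      b <- binding[binding$variant == v, , drop = FALSE]
      if (nrow(b) > 0 && any(!is.na(b$ddg))) {
        bm <- ddg_bmax(b)
      } else if (nrow(b) > 0) {
        warning("variant ", v, " has no usable binding ddG value",
                call. = FALSE)
      }
    }
    tibble(variant = v, ddg_fmax = fm$value, fmax_method = fm$method,
           ddg_bmax = bm$value, bmax_complex = bm$complex)
  })
  dplyr::bind_rows(rows)
}

#' Signed per-method, per-class ddG summaries
#'
#' Summarises a long ddG table by method (and complex, if present) and
#' clinical class: n, mean, median and sd of the *signed* values, matching
#' violin-plot statistics. No absolute values and no sign canonicalization
#' are applied here; pass pre-canonicalized values if a common scale is
#' wanted. Classes with a single member get `sd = 0` and a degeneracy
#' flag; classes with zero members are simply absent (a warning names
#' them).
#'
#' @param table Long tibble with `variant`, `method`, `ddg` (and
#'   optionally `complex`).
#' @param labels Named character vector mapping variant -> class.
#' @return Tibble with grouping columns plus `n`, `mean`, `median`, `sd`,
#'   `degenerate`.
#' @export
class_summary <- function(table, labels) {
  table$class <- unname(labels[table$variant])
  missing_lab <- is.na(table$class)
  if (any(missing_lab)) {
    warning(sum(missing_lab), " value(s) dropped: variant has no class label",
            call. = FALSE)
    table <- table[!missing_lab, , drop = FALSE]
  }
  grouping <- intersect(c("method", "complex", "class"), names(table))
  out <- table |>
    dplyr::filter(!is.na(.data$ddg)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$ddg),
      median = median(.data$ddg),
      sd = ifelse(dplyr::n() > 1, sd(.data$ddg), 0),
      degenerate = dplyr::n() == 1L,
      .groups = "drop"
    )
  absent <- setdiff(unique(labels), out$class)
  if (length(absent) > 0) {
    warning("class(es) with zero members omitted: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read ddG prediction tables
#'
#' `read_folding_table()` expects a wide TSV (`variant` plus one numeric
#' column per method) and returns it long (`variant`, `method`, `ddg`).
#' `read_binding_table()` expects a long TSV with columns `variant`,
#' `method`, `complex`, `ddg`. `read_method_metadata()` expects columns
#' `method`, `level`, `quantity`, `sign_convention`.
#'
#' @param path Input TSV path.
#' @return A tibble.
#' @export
read_folding_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"variant" %in% names(wide)) {
    stop("folding table lacks a 'variant' column", call. = FALSE)
  }
  tidyr::pivot_longer(wide, -"variant", names_to = "method",
                      values_to = "ddg")
}

#' @rdname read_folding_table
#' @export
read_binding_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("variant", "method", "complex", "ddg")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("binding table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' @rdname read_folding_table
#' @export
read_method_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
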