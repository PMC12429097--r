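# Parsing and normalization of protein-level variant notation and clinical
# category strings.

# Three-letter -> one-letter lookup for the 20 standard residues, built from
# Biostrings' code table, plus the stop spellings.
aa_three_to_one <- function() {
  code <- Biostrings::AMINO_ACID_CODE
  code <- code[names(code) %in% AA_STANDARD]
  out <- setNames(names(code), tolower(unname(code)))
  c(out, ter = "*")
}

#' Parse protein-change tokens
#'
#' Accepts the compact one-letter form (`"R178Q"`) and the HGVS three-letter
#' protein form with or without the `p.` prefix (`"p.Arg59Pro"`, `"p.Arg59*"`,
#' `"p.(Arg59*)"`). Stop-gain changes (`*`/`Ter` alternate) are parsed but
#' flagged as non-missense. Positions are 1-based; position 0, unknown
#' residue codes, identical reference and alternate residues, and otherwise
#' malformed tokens are errors.
#'
#' @param token Character vector of change tokens.
#' @return A tibble with one row per token: `token`, `ref`, `pos`, `alt`,
#'   `missense`.
#' @export
#' @examples
#' parse_protein_change(c("R178Q", "p.Arg59*"))
parse_protein_change <- function(token) {
  stopifnot(is.character(token))
  stripped <- sub("^p\\.", "", token, ignore.case = TRUE)
  stripped <- sub("^\\((.*)\\)$", "\\1", stripped)

  compact <- "^([A-Za-z])([0-9]+)([A-Za-z*])$"
  hgvs <- "^([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|\\*)$"
  three <- aa_three_to_one()

  parse_one <- function(tok, raw) {
    if (grepl(compact, tok)) {
      ref <- toupper(sub(compact, "\\1", tok))
      pos <- as.integer(sub(compact, "\\2", tok))
      alt <- toupper(sub(compact, "\\3", tok))
    } else if (grepl(hgvs, tok)) {
      ref3 <- tolower(sub(hgvs, "\\1", tok))
      alt3 <- tolower(sub(hgvs, "\\3", tok))
      if (alt3 == "*") alt3 <- "ter"
      pos <- as.integer(sub(hgvs, "\\2", tok))
      if (!ref3 %in% names(three) || ref3 == "ter") {
        stop("unknown residue code in token: ", raw, call. = FALSE)
      }
      if (!alt3 %in% names(three)) {
        stop("unknown residue code in token: ", raw, call. = FALSE)
      }
      ref <- three[[ref3]]
      alt <- three[[alt3]]
    } else {
      stop("malformed protein-change token: ", raw, call. = FALSE)
    }
    if (!ref %in% AA_STANDARD) {
      stop("unknown residue code in token: ", raw, call. = FALSE)
    }
    if (!(alt %in% AA_STANDARD || alt == "*")) {
      stop("unknown residue code in token: ", raw, call. = FALSE)
    }
    if (pos < 1L) {
      stop("invalid position (must be >= 1) in token: ", raw, call. = FALSE)
    }
    if (ref == alt) {
      stop("reference and alternate residues are identical in token: ", raw,
           call. = FALSE)
    }
    list(ref = ref, pos = pos, alt = alt)
  }

  parsed <- purrr::map2(stripped, token, parse_one)
  tibble(
    token = token,
    ref = purrr::map_chr(parsed, "ref"),
    pos = purrr::map_int(parsed, "pos"),
    alt = purrr::map_chr(parsed, "alt"),
    missense = purrr::map_chr(parsed, "alt") %in% AA_STANDARD
  )
}

#' Build compact variant identifiers
#'
#' @param ref,pos,alt Parsed change components.
#' @return Character vector like `"R178Q"`.
#' @export
variant_id <- function(ref, pos, alt) paste0(ref, pos, alt)

#' Harmonize germline classification strings
#'
#' Maps raw clinical classification strings onto the eight canonical
#' categories of [germline_levels()]. Matching is tolerant to case,
#' punctuation and spacing; the several spellings of the conflicting
#' category ("Conflicting classifications of pathogenicity", "conflicting
#' class of pathogenicity", ...) all map to `"conflicting"`. Unknown
#' strings are an error.
#'
#' @param x Character vector of raw classification strings.
#' @return Character vector of canonical category names.
#' @export
#' @examples
#' normalize_category(c("Benign/Likely benign", "Uncertain significance"))
normalize_category <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("[[:punct:]]+", " ", key)
  key <- gsub("[[:space:]]+", " ", key)
  key <- trimws(key)

  out <- character(length(key))
  lookup <- c(
    "benign" = "benign",
    "likely benign" = "likely_benign",
    "benign likely benign" = "benign_likely_benign",
    "uncertain significance" = "uncertain_significance",
    "variant of uncertain significance" = "uncertain_significance",
    "vus" = "uncertain_significance",
    "likely pathogenic" = "likely_pathogenic",
    "pathogenic likely pathogenic" = "pathogenic_likely_pathogenic",
    "pathogenic" = "pathogenic"
  )
  known <- key %in% names(lookup)
  out[known] <- lookup[key[known]]
  conflicting <- !known & startsWith(key, "conflicting")
  out[conflicting] <- "conflicting"
  bad <- !known & !conflicting
  if (any(bad)) {
    stop("unrecognized germline classification string(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}
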