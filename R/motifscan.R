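# Consensus phosphomotif scanning. CDKL5 phosphorylates its substrates at
# RPX[S/T][A/G/P/S]; the phosphoacceptor sits at the fourth slot of the
# 5-residue pattern, with serine preferred over threonine roughly 85:15.

#' Build a consensus-motif specification
#'
#' The pattern is a whitespace-separated sequence of position classes:
#' single residues (`R`), `X` for any standard residue, or a bracketed
#' class (`[ST]`, `[AGPS]`). The default is the CDKL5 consensus motif
#' `RPX[S/T][A/G/P/S]` with the phosphoacceptor at slot 4 (1-based).
#'
#' @param pattern Motif config string. Default `"R P X [ST] [AGPS]"`.
#' @param phospho_slot 1-based index of the phosphoacceptor slot. The
#'   class at this slot must be a subset of `{S, T}`.
#' @return An object of class `motif_spec`: a list with `classes` (list of
#'   character vectors) and `phospho_slot`.
#' @export
#' @examples
#' motif_spec()
motif_spec <- function(pattern = "R P X [ST] [AGPS]", phospho_slot = 4L) {
  tokens <- strsplit(trimws(pattern), "[[:space:]]+")[[1]]
  classes <- lapply(tokens, function(tok) {
    if (identical(toupper(tok), "X")) return(AA_STANDARD)
    if (grepl("^\\[[A-Za-z]+\\]$", tok)) {
      cls <- strsplit(toupper(gsub("\\[|\\]", "", tok)), "")[[1]]
    } else if (grepl("^[A-Za-z]$", tok)) {
      cls <- toupper(tok)
    } else {
      stop("malformed motif token: ", tok, call. = FALSE)
    }
    bad <- setdiff(cls, AA_STANDARD)
    if (length(bad) > 0) {
      stop("non-amino-acid residue(s) in motif class: ",
           paste(bad, collapse = ""), call. = FALSE)
    }
    cls
  })
  phospho_slot <- as.integer(phospho_slot)
  if (phospho_slot < 1L || phospho_slot > length(classes)) {
    stop("phospho_slot must index a pattern position", call. = FALSE)
  }
  if (!all(classes[[phospho_slot]] %in% c("S", "T"))) {
    stop("phosphoacceptor class must be a subset of {S, T}", call. = FALSE)
  }
  structure(list(classes = classes, phospho_slot = phospho_slot),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  pat <- vapply(x$classes, function(cls) {
    if (length(cls) == length(AA_STANDARD)) "X"
    else if (length(cls) == 1L) cls
    else paste0("[", paste(cls, collapse = "/"), "]")
  }, character(1))
  cat("<motif_spec> ", paste(pat, collapse = ""),
      " (phosphoacceptor at slot ", x$phospho_slot, ")\n", sep = "")
  invisible(x)
}

assert_aa_sequence <- function(sequence) {
  seq <- toupper(as.character(sequence))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_STANDARD)
  if (length(bad) > 0) {
    stop("sequence contains non-amino-acid character(s): ",
         paste(bad, collapse = ""), call. = FALSE)
  }
  seq
}

#' Scan a sequence for consensus-motif matches
#'
#' Reports every window position whose residues satisfy the motif position
#' classes, including overlapping matches, ordered by position. Matching is
#' case-insensitive on the input sequence.
#'
#' @param sequence Amino-acid string (or `AAString`).
#' @param spec A [motif_spec()].
#' @param sequence_id Identifier recorded in the hit table.
#' @param flank Flank width for the reported window (see
#'   [extract_window()]).
#' @return A tibble of hits: `seq_id`, `pos` (1-based phosphoacceptor
#'   position), `residue`, `match` (the matched k-mer), `window` (flanking
#'   window with the phosphoacceptor lowercased).
#' @export
#' @examples
#' scan_consensus("TIRERPSSAIYPS")
scan_consensus <- function(sequence, spec = motif_spec(),
                           sequence_id = "seq", flank = 7L) {
  seq <- assert_aa_sequence(sequence)
  k <- length(spec$classes)
  empty <- tibble(seq_id = character(), pos = integer(),
                  residue = character(), match = character(),
                  window = character())
  if (nchar(seq) < k) return(empty)

  regex <- paste0("(?=", paste(vapply(spec$classes, function(cls) {
    if (length(cls) == length(AA_STANDARD)) "."
    else paste0("[", paste(cls, collapse = ""), "]")
  }, character(1)), collapse = ""), ")")
  m <- gregexpr(regex, seq, perl = TRUE)[[1]]
  starts <- as.integer(m)
  starts <- starts[starts > 0]
  if (length(starts) == 0) return(empty)

  pos <- starts + spec$phospho_slot - 1L
  tibble(
    seq_id = sequence_id,
    pos = pos,
    residue = substring(seq, pos, pos),
    match = substring(seq, starts, starts + k - 1L),
    window = vapply(pos, function(p) extract_window(seq, p, flank),
                    character(1))
  )
}

#' Extract a phosphosite-centered window
#'
#' Returns the subsequence from `max(1, pos - flank)` to
#' `min(L, pos + flank)` with the phosphoacceptor residue lowercased;
#' windows are silently truncated at the sequence termini.
#'
#' @param sequence Amino-acid string.
#' @param phospho_position 1-based position of the phosphoacceptor.
#' @param flank Number of residues on each side (default 7).
#' @return Window string with exactly one lowercase residue.
#' @export
#' @examples
#' extract_window("QSPKRPRSPGSNS", 8, 7)
extract_window <- function(sequence, phospho_position, flank = 7L) {
  seq <- toupper(as.character(sequence))
  n <- nchar(seq)
  p <- as.integer(phospho_position)
  if (p < 1L || p > n) {
    stop("phospho_position out of range: ", phospho_position, call. = FALSE)
  }
  if (flank < 0L) stop("flank must be >= 0", call. = FALSE)
  lo <- max(1L, p - as.integer(flank))
  hi <- min(n, p + as.integer(flank))
  win <- substring(seq, lo, hi)
  at <- p - lo + 1L
  paste0(
    substring(win, 1L, at - 1L),
    tolower(substring(win, at, at)),
    substring(win, at + 1L, nchar(win))
  )
}

#' Serine/threonine preference among motif hits
#'
#' @param hits Hit tibble from [scan_consensus()] (or anything with a
#'   `residue` column of `"S"`/`"T"` values).
#' @return Named numeric vector `c(serine = ..., threonine = ...)`, summing
#'   to 1.
#' @export
phospho_preference <- function(hits) {
  if (nrow(hits) == 0) stop("empty hit list", call. = FALSE)
  res <- hits$residue
  c(serine = mean(res == "S"), threonine = mean(res == "T"))
}

#' Scan a FASTA file (or AAStringSet) for consensus motifs
#'
#' @param fasta Path to a FASTA file or a `Biostrings::AAStringSet`.
#' @param spec A [motif_spec()].
#' @param flank Flank width for reported windows.
#' @return Combined hit tibble across records.
#' @export
scan_fasta <- function(fasta, spec = motif_spec(), flank = 7L) {
  seqs <- if (inherits(fasta, "AAStringSet")) {
    fasta
  } else {
    Biostrings::readAAStringSet(fasta)
  }
  hits <- purrr::imap(as.character(seqs), function(s, id) {
    scan_consensus(s, spec, sequence_id = id, flank = flank)
  })
  dplyr::bind_rows(hits)
}
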