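# Independent oracles and small fixture builders shared across tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa_seq <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# Brute-force consensus scanner: tests every k-mer against the position
# classes, independent of the regex-based implementation.
brute_force_scan <- function(sequence, classes = list("R", "P", AA20,
                                                      c("S", "T"),
                                                      c("A", "G", "P", "S")),
                             phospho_slot = 4L) {
  seq <- toupper(sequence)
  k <- length(classes)
  n <- nchar(seq)
  hits <- integer(0)
  if (n >= k) {
    for (start in seq_len(n - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!substring(seq, start + j - 1L, start + j - 1L) %in%
              classes[[j]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits <- c(hits, start + phospho_slot - 1L)
    }
  }
  hits
}

# Build a record tibble of n distinct synthetic variants consistent with a
# reference sequence, for curation tests.
make_records <- function(n, reference, category = "uncertain_significance",
                         positions = NULL) {
  L <- nchar(reference)
  if (is.null(positions)) positions <- sample(L, n, replace = FALSE)
  ref <- substring(reference, positions, positions)
  alt <- vapply(ref, function(r) sample(setdiff(AA20, r), 1), character(1))
  tibble::tibble(
    ref = unname(ref), pos = as.integer(positions), alt = unname(alt),
    missense = TRUE, consequence = "missense_variant",
    category = category, af = NA_real_
  )
}
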