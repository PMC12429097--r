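# Reference tables for the CDKL5 analysis: domain geography, published
# germline-category tallies, class-conditional ddG means, substrate motif
# windows, and the mechanism partition lists. These are the published inputs
# the pipeline consumes; everything derived from them is computed at run time.

AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

GERMLINE_LEVELS <- c(
  "benign",
  "likely_benign",
  "benign_likely_benign",
  "uncertain_significance",
  "conflicting",
  "likely_pathogenic",
  "pathogenic_likely_pathogenic",
  "pathogenic"
)

#' Canonical germline classification categories
#'
#' The eight harmonized clinical categories used throughout the package,
#' ordered from benign to pathogenic. `benign_group()` returns the subset
#' treated as "benign" under the binary grouping used for predictor
#' evaluation (benign, benign/likely benign, likely benign); every other
#' category counts as non-benign.
#'
#' @return Character vector of category names.
#' @export
#' @examples
#' germline_levels()
#' benign_group()
germline_levels <- function() GERMLINE_LEVELS

#' @rdname germline_levels
#' @export
benign_group <- function() {
  c("benign", "likely_benign", "benign_likely_benign")
}

#' Functional regions of the CDKL5 protein
#'
#' Default region annotation set with 1-based inclusive residue coordinates:
#' the N-terminal kinase domain (1-302) containing the ATP-binding site
#' (19-43), the S/T-kinase active site (131-143), the TEY activation motif
#' (169-171) and the MAPK insert (297); plus the C-terminal nuclear
#' localization signals (NLS1 312-315, NLS2 784-789) and the nuclear export
#' signal (NES 836-845). Residue 302 is inside the kinase domain.
#'
#' @return A tibble with columns `name`, `start`, `end`.
#' @export
cdkl5_regions <- function() {
  tribble(
    ~name,            ~start, ~end,
    "kinase_domain",       1L, 302L,
    "atp_binding",        19L,  43L,
    "st_active_site",    131L, 143L,
    "tey_motif",         169L, 171L,
    "mapk_insert",       297L, 297L,
    "nls1",              312L, 315L,
    "nls2",              784L, 789L,
    "nes",               836L, 845L
  )
}

#' Published germline-category tallies for curated CDKL5 missense variants
#'
#' Counts per harmonized germline category for the curated variant set:
#' 156 variants across the full-length protein (residues 1-960), of which
#' 112 fall in the kinase domain (residues 1-302). These tallies drive the
#' synthetic-data generator defaults and the bookkeeping checks.
#'
#' @param scope `"kinase"` (default) or `"full"`.
#' @return Named integer vector over [germline_levels()].
#' @export
#' @examples
#' sum(cdkl5_category_counts("kinase"))  # 112
#' sum(cdkl5_category_counts("full"))    # 156
cdkl5_category_counts <- function(scope = c("kinase", "full")) {
  scope <- match.arg(scope)
  counts <- switch(scope,
    kinase = c(4L, 1L, 12L, 30L, 10L, 22L, 24L, 9L),
    full   = c(20L, 10L, 15L, 43L, 13L, 22L, 24L, 9L)
  )
  setNames(counts, GERMLINE_LEVELS)
}

#' Class-conditional folding ddG means by prediction method
#'
#' Mean predicted folding free-energy change (kcal/mol, on each method's
#' native sign convention, negative = destabilizing) for pathogenic and
#' benign kinase-domain variants, per prediction method. Structure-based
#' methods are the default inputs to the ddG_Fmax statistic. Means for
#' DDMut, DDGun (structure) and INPS/DDGun (sequence) are package-chosen
#' values consistent with the qualitative behaviour of those tools (DDMut
#' tracks mCSM/I-Mutant2.0; DDGun is neutral on benign variants).
#'
#' @param level `"structure"` (default) or `"sequence"`.
#' @return Tibble with columns `method`, `level`, `pathogenic`, `benign`.
#' @export
folding_class_means <- function(level = c("structure", "sequence")) {
  level <- match.arg(level)
  tab <- tribble(
    ~method,        ~level,      ~pathogenic, ~benign,
    "I-Mutant2.0",  "structure", -1.330,       0.002,
    "mCSM",         "structure", -1.025,      -0.258,
    "INPS",         "structure", -0.928,       0.100,
    "DDMut",        "structure", -1.100,      -0.150,
    "DDGun",        "structure", -0.900,       0.000,
    "I-Mutant2.0",  "sequence",  -1.332,      -0.183,
    "DDGemb",       "sequence",  -1.364,      -0.030,
    "SAAFEC-SEQ",   "sequence",  -1.341,      -0.870,
    "INPS",         "sequence",  -0.700,      -0.100,
    "DDGun",        "sequence",  -0.400,       0.000
  )
  tab[tab$level == level, ]
}

#' Class-conditional binding ddG means by method and CDKL5-partner complex
#'
#' Mean predicted binding free-energy change (kcal/mol, each method's
#' native sign convention) for pathogenic and benign kinase-domain variants,
#' for the four modelled CDKL5-substrate complexes (AMPH1, GATAD2A, SOX9,
#' ZNF219). iSEE and SAAMBE-3D report mutant-minus-wildtype values; mCSM-PPI
#' and DDMutPPI report the opposite convention, hence their negative means.
#'
#' @return Tibble with columns `method`, `complex`, `pathogenic`, `benign`.
#' @export
binding_class_means <- function() {
  tribble(
    ~method,      ~complex,   ~pathogenic, ~benign,
    "iSEE",       "SOX9",      1.86,        1.25,
    "mCSM-PPI",   "SOX9",     -0.91,       -0.53,
    "DDMutPPI",   "SOX9",     -0.53,       -0.13,
    "SAAMBE-3D",  "SOX9",      0.44,        0.22,
    "iSEE",       "AMPH1",     2.38,        1.35,
    "mCSM-PPI",   "AMPH1",    -0.90,       -0.55,
    "DDMutPPI",   "AMPH1",    -0.30,       -0.07,
    "SAAMBE-3D",  "AMPH1",     0.29,        0.15,
    "iSEE",       "GATAD2A",   2.56,        1.26,
    "mCSM-PPI",   "GATAD2A",  -0.73,       -0.50,
    "DDMutPPI",   "GATAD2A",  -0.42,       -0.13,
    "SAAMBE-3D",  "GATAD2A",   0.29,        0.13,
    "iSEE",       "ZNF219",    2.20,        1.02,
    "mCSM-PPI",   "ZNF219",   -0.74,       -0.52,
    "DDMutPPI",   "ZNF219",   -0.48,       -0.11,
    "SAAMBE-3D",  "ZNF219",    0.35,        0.17
  )
}

#' Default ddG prediction-method metadata
#'
#' One row per method with its input level (sequence/structure), the
#' quantity it predicts (folding/binding) and, for binding methods, the
#' sign convention: iSEE and SAAMBE-3D report ddG = dG_mutant - dG_wildtype,
#' while mCSM-PPI and DDMutPPI use the opposite definition.
#'
#' @return Tibble with columns `method`, `level`, `quantity`,
#'   `sign_convention`.
#' @export
method_metadata <- function() {
  folding <- folding_class_means("structure")
  dplyr::bind_rows(
    tibble(
      method = folding$method,
      level = "structure",
      quantity = "folding",
      sign_convention = "mutant_minus_wildtype"
    ),
    tribble(
      ~method,      ~level,      ~quantity, ~sign_convention,
      "iSEE",       "structure", "binding", "mutant_minus_wildtype",
      "SAAMBE-3D",  "structure", "binding", "mutant_minus_wildtype",
      "mCSM-PPI",   "structure", "binding", "wildtype_minus_mutant",
      "DDMutPPI",   "structure", "binding", "wildtype_minus_mutant"
    )
  )
}

#' Candidate CDKL5 substrates and their phosphosite windows
#'
#' The curated substrate table: UniProt accession, gene symbol, reported
#' phosphosite, the display window around the site (phosphoacceptor in
#' lowercase) and whether the window carries the consensus motif
#' RPX[S/T][A/G/P/S]. Substrates supported by biochemical evidence only
#' (no consensus match) have `has_motif = FALSE`; windows marked `NA` were
#' not reported. MAP1S carries two reported sites and contributes two rows.
#'
#' @return Tibble with columns `uniprot`, `gene`, `psite`, `window`,
#'   `has_motif`.
#' @export
cdkl5_substrates <- function() {
  tribble(
    ~uniprot, ~gene,      ~psite,  ~window,            ~has_motif,
    "Q92974", "ARHGEF2",  "S122",  "TIRERPSsAIYPS",    TRUE,
    "P49418", "AMPH1",    "S293",  "PAPARPRsPSQTR",    TRUE,
    "Q9UPN4", "CEP131",   "S35",   "PVSRRPGsAATTK",    TRUE,
    "Q8TDM6", "DLG5",     "S1115", "QKRRRPKsAPSFR",    TRUE,
    "Q14241", "ELOA",     "S311",  "EENRRPPsGDNAR",    TRUE,
    "Q96L91", "EP400",    "S729",  "SPVNRPSsATNKA",    TRUE,
    "Q66K74", "MAP1S",    "S871",  "KAPARPSsASATP",    TRUE,
    "Q66K74", "MAP1S",    "S900",  "DRASRPLsARSEP",    TRUE,
    "Q15555", "EB2",      "S222",  "STPSRPSsAKRAS",    TRUE,
    "Q8TAP9", "TTDN1",    "S40",   "GGGPRPPsPRDGY",    TRUE,
    "P78347", "GTF2I",    "S674",  "QSPKRPRsPGSNS",    TRUE,
    "Q8TAP8", "PPP1R35",  "S52",   "SLSPRPDsPQPRH",    TRUE,
    "Q86YP4", "GATAD2A",  "S100",  "KSERRPPsPDVIV",    TRUE,
    "Q9P2Y4", "ZNF219",   "S114",  "HQPERPRsPAARL",    TRUE,
    "Q15878", "CACNA1E",  "S14",   "AVVARPGsGDGD",     TRUE,
    "P56524", "HDAC4",    "S632",  "RPLSRAQsSPASAtF",  FALSE,
    "Q9HCJ2", "NGL-1",    "S631",  "PLLIRMNsKDNVQET",  FALSE,
    "P48436", "SOX9",     "S199",  "ATEQTHIsPNAIFKA",  FALSE,
    "Q13501", "p62",      "T269",  "RSRLTPVsPESS",     FALSE,
    "Q13501", "p62",      "S272",  "GGKRSRLtPVSP",     FALSE,
    "P26358", "DNMT1",    NA,      NA,                 FALSE,
    "P84022", "SMAD3",    NA,      NA,                 FALSE,
    "P46940", "IQGAP1",   NA,      NA,                 FALSE,
    "P51608", "MeCP2",    NA,      NA,                 FALSE,
    "P78352", "PSD95",    NA,      NA,                 FALSE,
    "A0MZ66", "SHTN1",    NA,      NA,                 FALSE
  )
}

#' Pathogenic CDKL5 kinase-domain variants by dominant thermodynamic mechanism
#'
#' The published mechanism partition of thermodynamically reclassified
#' pathogenic kinase-domain variants: `folding` for variants whose folding
#' destabilization exceeds their binding destabilization
#' (ddG_Fmax > ddG_Bmax, candidates for stability-enhancing drugs) and
#' `binding` for variants with equal or higher binding destabilization
#' (ddG_Fmax <= ddG_Bmax, candidates for binding-restoring drugs).
#'
#' @return Tibble with columns `variant`, `mechanism`.
#' @export
cdkl5_mechanism_variants <- function() {
  folding <- c(
    "F13S", "G20D", "G20R", "E21G", "G22E", "G22V", "Y24C", "V27A", "C30Y",
    "R31G", "T35I", "I41F", "K42R", "L64P", "L67F", "L67P", "N71D", "N71S",
    "I72N", "I72T", "K76E", "R80H", "G83V", "L97P", "V107D", "Y117C",
    "L119R", "A122T", "W125C", "C126Y", "H127R", "V132G", "D135G", "P138L",
    "L141F", "I143N", "I143V", "H145Y", "N146S", "K150R", "C152F", "C152R",
    "D153G", "G155D", "A157P", "A157V", "R158H", "R158P", "R175S", "W176C",
    "W176G", "W176R", "Y177C", "Y177S", "R178Q", "S179F", "E181A", "L182P",
    "L184H", "A186T", "D193G", "D193H", "D193N", "G198D", "G198R", "C199R",
    "L201P", "G202E", "E203D", "E203K", "G207E", "P209R", "G213E", "Q219K",
    "Q219P", "L220P", "K225R", "L227R", "Y262H", "L271P", "R285S", "T288I",
    "C291R", "C291Y", "T296A", "L302F"
  )
  binding <- c(
    "G20V", "G25R", "A40V", "R59P", "R65Q", "R80L", "H127Y", "D153V",
    "V172I", "A173D", "T174N", "R178P", "R178W", "P180L", "D193V", "S196L",
    "G213R"
  )
  tibble(
    variant = c(folding, binding),
    mechanism = rep(c("folding", "binding"), c(length(folding), length(binding)))
  )
}

#' Published training ranges of the thermodynamic statistics
#'
#' Observed ranges of ddG_Fmax and ddG_Bmax (kcal/mol) over the strictly
#' annotated kinase-domain training variants (4 benign, 9 pathogenic).
#' The midpoints of the inner extrema give the classification thresholds:
#' (0.68 + 0.86)/2 = 0.77 kcal/mol for folding and (0.82 + 0.95)/2 = 0.885
#' (displayed 0.88) kcal/mol for binding.
#'
#' @return Tibble with columns `statistic`, `class`, `min`, `max`.
#' @export
cdkl5_training_ranges <- function() {
  tribble(
    ~statistic, ~class,       ~min, ~max,
    "ddg_fmax", "benign",     0.09, 0.68,
    "ddg_fmax", "pathogenic", 0.86, 3.42,
    "ddg_bmax", "benign",     0.45, 0.82,
    "ddg_bmax", "pathogenic", 0.95, 1.55
  )
}
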