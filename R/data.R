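# Bundled reference data: the alca cyclotide sequences and the published
# A. cauliflora derivatization mass table used throughout examples and
# validation.

#' The alca cyclotide sequences
#'
#' The two bracelet cyclotides isolated from *Allexis cauliflora*: alca 1
#' (31 residues, native \[M+H\]+ 3211.4) and alca 2 (30 residues, native
#' \[M+H\]+ 3084.2).  Both are head-to-tail cyclic with three disulfides;
#' the sequences are written starting after the native ligation site, so
#' each ends with its ligation Asp/Asn.
#'
#' @param cys_state Cysteine state of the returned peptides:
#'   `"oxidized"` (native, 3 disulfides; default) or
#'   `"carbamidomethylated"` (the state in which digests and MS/MS are
#'   performed).
#' @return Named list of two cyclic [peptide()]s, `alca1` and `alca2`.
#' @examples
#' sapply(alca_peptides(), function(p) mz(peptide_neutral_mass(p)))
#' @export
alca_peptides <- function(cys_state = c("oxidized",
                                        "carbamidomethylated")) {
  cys_state <- match.arg(cys_state)
  n_ss <- if (cys_state == "oxidized") 3L else 0L
  list(
    alca1 = peptide("GVIPCGESCVFIPCISAAIGCSCKNKVCYRD", topology = "cyclic",
                    cys_state = cys_state, n_disulfides = n_ss),
    alca2 = peptide("GIPCGESCVFIPCISGVLGCSCSNKVCYRN", topology = "cyclic",
                    cys_state = cys_state, n_disulfides = n_ss)
  )
}

#' Published A. cauliflora derivatization mass table
#'
#' The 18 monoisotopic \[M+H\]+ signals reported for the *A. cauliflora*
#' peptide-enriched extract in each of the four derivatization states
#' (native, reduced, carbamidomethylated, GluC-processed), at one-decimal
#' precision as published.  Feeding the four columns to [match_series()]
#' reproduces the screening result that all 18 series are six-cysteine
#' cyclic peptides.
#'
#' @return Data frame with numeric columns `native`, `reduced`,
#'   `alkylated`, `linearized` (18 rows).
#' @examples
#' tab <- acauliflora_screen_table()
#' rep <- screen_report(match_series(
#'   peak_list(tab$native, label = "native"),
#'   peak_list(tab$reduced, label = "reduced"),
#'   peak_list(tab$alkylated, label = "alkylated"),
#'   peak_list(tab$linearized, label = "linearized"),
#'   screen_params("dalton", 0.2)))
#' rep$counts
#' @export
acauliflora_screen_table <- function() {
  path <- system.file("extdata", "acauliflora_derivatization_mz.csv",
                      package = "cyclopep", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}
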