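# Monoisotopic mass arithmetic for cyclic/linear peptides across cysteine
# derivatization states.  All masses in Da, all m/z singly protonated unless
# a charge is given explicitly.

# Standard monoisotopic residue masses, 6 decimals.  Non-canonical letters
# (B, Z, X, U, O, J) are deliberately absent: they are rejected, not
# approximated.
.AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.MASS_WATER  <- 18.010565   # H2O, condensed out on peptide-bond formation
.MASS_PROTON <- 1.007276    # charge carrier for [M + zH]z+
.MASS_H      <- 1.007825    # hydrogen atom, gained per thiol on reduction
.MASS_CAM    <- 57.021464   # S-carbamidomethyl on a reduced Cys (iodoacetamide)
.MASS_NH3    <- 17.026549   # ammonia neutral loss
# reduction (+1 H per Cys) followed by carbamidomethylation (+57.0215 per Cys)
# relative to the disulfide-bonded native form:
.DELTA_ALK_NATIVE <- .MASS_H + .MASS_CAM   # 58.029289 per Cys

#' Monoisotopic mass constants
#'
#' The fixed physical constants used throughout the package: monoisotopic
#' residue masses for the 20 canonical amino acids and the deltas of the
#' cysteine derivatization chemistry (reduction, S-carbamidomethylation,
#' proteolytic ring opening).
#'
#' @return A named list with elements `residue_mass` (named numeric vector,
#'   one-letter codes), `water`, `proton`, `h_atom`, `cam_delta`,
#'   `reduction_delta_per_cys`, `alkylation_from_native_per_cys`,
#'   `ring_open_delta`, `nh3` (all Da).
#' @examples
#' mass_constants()$alkylation_from_native_per_cys * 6  # the 6-Cys CAM shift
#' @export
mass_constants <- function() {
  list(
    residue_mass = .AA_MONO,
    water = .MASS_WATER,
    proton = .MASS_PROTON,
    h_atom = .MASS_H,
    cam_delta = .MASS_CAM,
    reduction_delta_per_cys = .MASS_H,
    alkylation_from_native_per_cys = .DELTA_ALK_NATIVE,
    ring_open_delta = .MASS_WATER,
    nh3 = .MASS_NH3
  )
}

# Validate an amino acid sequence; returns the uppercased string or stops
# naming the first offending position.
.check_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop(what, " must be a single non-empty character string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.AA_MONO))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d of %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  sequence
}

#' Construct a peptide
#'
#' The unit of all mass arithmetic: an amino acid sequence together with its
#' backbone topology (head-to-tail cyclic or linear) and the chemical state
#' of its cysteines.
#'
#' @param sequence Uppercase string over the 20 canonical one-letter codes.
#'   Lowercase input is uppercased; non-canonical letters (B, Z, X, U, O, J)
#'   are rejected with the offending position.
#' @param topology `"linear"` or `"cyclic"`.  A cyclic sequence must have at
#'   least 3 residues.
#' @param cys_state `"reduced"` (free thiols), `"oxidized"` (disulfide
#'   bonded), or `"carbamidomethylated"` (S-CAM on the reduced thiols).
#' @param n_disulfides Number of disulfide bonds; only meaningful (and only
#'   allowed to be nonzero) when `cys_state = "oxidized"`, and bounded by
#'   half the cysteine count.
#' @return An object of class `"peptide"`.
#' @examples
#' alca1 <- peptide("GVIPCGESCVFIPCISAAIGCSCKNKVCYRD",
#'                  topology = "cyclic", cys_state = "oxidized",
#'                  n_disulfides = 3)
#' peptide_neutral_mass(alca1)
#' @export
peptide <- function(sequence,
                    topology = c("linear", "cyclic"),
                    cys_state = c("reduced", "oxidized", "carbamidomethylated"),
                    n_disulfides = 0L) {
  sequence <- .check_sequence(sequence)
  topology <- match.arg(topology)
  cys_state <- match.arg(cys_state)
  n_disulfides <- as.integer(n_disulfides)
  if (is.na(n_disulfides) || n_disulfides < 0L) {
    stop("n_disulfides must be a non-negative integer", call. = FALSE)
  }
  n_cys <- .count_char(sequence, "C")
  if (cys_state == "oxidized") {
    if (2L * n_disulfides > n_cys) {
      stop(sprintf("%d disulfides require %d cysteines; sequence has %d",
                   n_disulfides, 2L * n_disulfides, n_cys), call. = FALSE)
    }
  } else if (n_disulfides != 0L) {
    stop("n_disulfides must be 0 unless cys_state is 'oxidized'",
         call. = FALSE)
  }
  if (topology == "cyclic" && nchar(sequence) < 3L) {
    stop("a cyclic peptide must have at least 3 residues", call. = FALSE)
  }
  structure(
    list(sequence = sequence, topology = topology, cys_state = cys_state,
         n_disulfides = n_disulfides),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s %s (%d aa, %d Cys", x$topology, x$sequence,
              nchar(x$sequence), .count_char(x$sequence, "C")))
  cat(sprintf(", %s", x$cys_state))
  if (x$cys_state == "oxidized") cat(sprintf(", %d S-S", x$n_disulfides))
  cat(sprintf(")\n  neutral M = %.4f Da, [M+H]+ = %.4f\n",
              peptide_neutral_mass(x), mz(peptide_neutral_mass(x), 1L)))
  invisible(x)
}

.count_char <- function(s, ch) {
  lengths(regmatches(s, gregexpr(ch, s, fixed = TRUE)))
}

.residue_vector <- function(sequence) {
  .AA_MONO[strsplit(sequence, "", fixed = TRUE)[[1L]]]
}

#' Neutral monoisotopic mass of a peptide
#'
#' Linear peptides are the residue-mass sum plus one water; head-to-tail
#' cyclic peptides omit the water.  The oxidized (disulfide-bonded) state
#' subtracts two hydrogen atoms per disulfide; the carbamidomethylated state
#' adds the S-CAM delta (+57.021464 Da) per cysteine on top of the reduced
#' form.
#'
#' @param p A [peptide()].
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_neutral_mass <- function(p) {
  stopifnot(inherits(p, "peptide"))
  m <- sum(.residue_vector(p$sequence))
  if (p$topology == "linear") m <- m + .MASS_WATER
  if (p$cys_state == "oxidized") {
    m <- m - 2 * .MASS_H * p$n_disulfides
  } else if (p$cys_state == "carbamidomethylated") {
    m <- m + .MASS_CAM * .count_char(p$sequence, "C")
  }
  m
}

#' m/z of a neutral mass at a given positive charge
#'
#' `(M + z * proton) / z` with the proton mass 1.007276 Da.  The MALDI
#' context of this package is singly charged; higher charges are supported
#' for completeness.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge state (default 1).
#' @return m/z value.
#' @export
mz <- function(neutral_mass, charge = 1L) {
  charge <- as.integer(charge)
  if (any(is.na(charge)) || any(charge < 1L)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (neutral_mass + charge * .MASS_PROTON) / charge
}

#' Mass delta of a cysteine derivatization step
#'
#' The three steps of the cyclotide identification chemistry: disulfide
#' reduction (+1.007825 Da per Cys), alkylation relative to the *native*
#' disulfide form (+58.029289 Da per Cys, i.e. reduction plus
#' S-carbamidomethylation), and proteolytic ring opening of a cyclic
#' backbone (+18.010565 Da once, independent of `n_cys`).
#'
#' @param n_cys Number of cysteines reacted (non-negative integer).
#' @param step One of `"reduce"`, `"alkylate_from_native"`, `"ring_open"`.
#' @return Mass shift in Da.
#' @examples
#' derivatization_delta(6, "alkylate_from_native")  # 348.17574
#' @export
derivatization_delta <- function(n_cys,
                                 step = c("reduce", "alkylate_from_native",
                                          "ring_open")) {
  step <- match.arg(step)
  n_cys <- as.integer(n_cys)
  if (is.na(n_cys) || n_cys < 0L) {
    stop("n_cys must be a non-negative integer", call. = FALSE)
  }
  switch(step,
    reduce = n_cys * .MASS_H,
    alkylate_from_native = n_cys * .DELTA_ALK_NATIVE,
    ring_open = .MASS_WATER
  )
}

#' Molar extinction coefficient at 280 nm
#'
#' The standard composition-based estimate: 1490 per Tyr, 5500 per Trp and
#' 125 per cystine (disulfide-bonded Cys pair), in M^-1 cm^-1.
#'
#' @param sequence Amino acid sequence (one-letter codes).
#' @param n_cystine Number of cystines (disulfide bonds); must satisfy
#'   `2 * n_cystine <= number of Cys`.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @examples
#' extinction_coefficient_280("GVIPCGESCVFIPCISAAIGCSCKNKVCYRD", 3)  # 1865
#' @export
extinction_coefficient_280 <- function(sequence, n_cystine = 0L) {
  sequence <- .check_sequence(sequence)
  n_cystine <- as.integer(n_cystine)
  if (is.na(n_cystine) || n_cystine < 0L) {
    stop("n_cystine must be a non-negative integer", call. = FALSE)
  }
  if (2L * n_cystine > .count_char(sequence, "C")) {
    stop(sprintf("%d cystines require %d cysteines; sequence has %d",
                 n_cystine, 2L * n_cystine, .count_char(sequence, "C")),
         call. = FALSE)
  }
  1490 * .count_char(sequence, "Y") +
    5500 * .count_char(sequence, "W") +
    125 * n_cystine
}

#' Signed relative mass error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `1e6 * (observed - theoretical) / theoretical`, signed.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}
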