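# In-silico site-specific proteolysis of cyclic and linear peptides.
#
# Coordinates are 1-based indices into the sequence as written, where
# position 1 is the first residue after the native ligation site of a
# cyclic parent; fragments of cyclic parents wrap modulo the parent length.

#' Define a cleavage rule
#'
#' @param name Enzyme name.
#' @param cleave_after Residues after which the peptide bond is cleaved.
#' @param blocked_by_next Residues that block cleavage when they follow the
#'   site (e.g. proline for trypsin).
#' @param max_missed Default maximum number of uncut internal sites in a
#'   reported partial product.
#' @return A list of class `"cleavage_rule"`.
#' @export
cleavage_rule <- function(name, cleave_after, blocked_by_next = character(0),
                          max_missed = 2L) {
  cleave_after <- unique(toupper(cleave_after))
  blocked_by_next <- unique(toupper(blocked_by_next))
  if (!length(cleave_after) ||
      !all(cleave_after %in% names(mass_constants()$residue_mass))) {
    stop("cleave_after must be a non-empty set of canonical residues",
         call. = FALSE)
  }
  if (length(blocked_by_next) &&
      !all(blocked_by_next %in% names(mass_constants()$residue_mass))) {
    stop("blocked_by_next must contain canonical residues", call. = FALSE)
  }
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) {
    stop("max_missed must be a non-negative integer", call. = FALSE)
  }
  structure(list(name = name, cleave_after = cleave_after,
                 blocked_by_next = blocked_by_next, max_missed = max_missed),
            class = "cleavage_rule")
}

#' Built-in protease specificities
#'
#' GluC cleaves after Glu; trypsin after Lys/Arg unless followed by Pro;
#' chymotrypsin after Phe/Tyr/Trp/Leu/Met (never after Ile, whose
#' beta-branched side chain hinders the enzyme) or, in `strict` mode, after
#' the aromatic residues only.
#'
#' @param max_missed Default missed-cleavage allowance for the rule.
#' @param strict For chymotrypsin, restrict specificity to F/Y/W.
#' @return A [cleavage_rule()].
#' @export
gluc_rule <- function(max_missed = 2L) {
  cleavage_rule("GluC", "E", max_missed = max_missed)
}

#' @rdname gluc_rule
#' @export
trypsin_rule <- function(max_missed = 2L) {
  cleavage_rule("trypsin", c("K", "R"), blocked_by_next = "P",
                max_missed = max_missed)
}

#' @rdname gluc_rule
#' @export
chymotrypsin_rule <- function(max_missed = 2L, strict = FALSE) {
  res <- if (strict) c("F", "Y", "W") else c("F", "Y", "W", "L", "M")
  cleavage_rule("chymotrypsin", res, max_missed = max_missed)
}

#' Cleavage sites of a protease on a peptide
#'
#' A site is a position `i` (1-based) such that the bond *after* residue `i`
#' is cleaved: residue `i` is in the rule's `cleave_after` set and the next
#' residue (wrapping for cyclic parents; for linear parents only if it
#' exists) is not in `blocked_by_next`.  For a linear parent the C-terminal
#' residue is never a site (there is no bond after it).
#'
#' @param p A [peptide()].
#' @param rule A [cleavage_rule()].
#' @return Sorted integer vector of 1-based site positions.
#' @export
cleavage_sites <- function(p, rule) {
  stopifnot(inherits(p, "peptide"), inherits(rule, "cleavage_rule"))
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  idx <- which(chars %in% rule$cleave_after)
  if (p$topology == "linear") idx <- idx[idx < n]
  if (length(rule$blocked_by_next) && length(idx)) {
    nxt <- chars[ifelse(idx == n, 1L, idx + 1L)]
    idx <- idx[!nxt %in% rule$blocked_by_next]
  }
  idx
}

.wrap_substring <- function(chars, start, len) {
  n <- length(chars)
  paste(chars[((start - 1L + seq_len(len) - 1L) %% n) + 1L], collapse = "")
}

.fragment_mass <- function(sequence, cys_state) {
  cst <- mass_constants()
  m <- sum(cst$residue_mass[strsplit(sequence, "", fixed = TRUE)[[1L]]]) +
    cst$water
  if (cys_state == "carbamidomethylated") {
    m <- m + cst$cam_delta * .count_char(sequence, "C")
  }
  m
}

#' Digest a peptide in silico
#'
#' For a cyclic parent with `k` sites the complete digest yields `k`
#' fragments, each running from one site's successor to the next site
#' (wrapping); partial products with up to `max_missed` uncut internal
#' sites are also emitted, and the `k` full-length single-cut linear forms
#' (one per site) are always emitted and flagged via the `full_length`
#' column even when they exceed `max_missed`.  A cyclic parent with no
#' sites yields nothing (the backbone stays closed).  Linear parents follow
#' standard digestion.  Every fragment mass is computed as a linear peptide
#' (one water per cut is gained); cysteines carry the CAM adduct when the
#' parent is carbamidomethylated, and free thiols otherwise (a digest of an
#' oxidized parent cannot assign disulfides to fragments, so masses are
#' reported for the reduced form).
#'
#' @param p A [peptide()]; carbamidomethylated is the state in which digest
#'   masses are normally interpreted.
#' @param rule A [cleavage_rule()].
#' @param max_missed Missed-cleavage allowance; defaults to the rule's.
#' @return A data frame of class `"digest_fragments"`: `sequence`, `start`
#'   (1-based position in the parent as written), `length`, `missed`,
#'   `full_length` (the designated single-cut product of a cyclic parent),
#'   `n_cys`, `neutral_mass`, `mz1`, sorted by `start` then `length`.
#' @examples
#' alca1_cam <- peptide("GVIPCGESCVFIPCISAAIGCSCKNKVCYRD", "cyclic",
#'                      "carbamidomethylated")
#' digest_peptide(alca1_cam, gluc_rule())      # single ring-opened product
#' digest_peptide(alca1_cam, trypsin_rule())   # Lys/Arg fragments
#' @export
digest_peptide <- function(p, rule, max_missed = rule$max_missed) {
  stopifnot(inherits(p, "peptide"), inherits(rule, "cleavage_rule"))
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) {
    stop("max_missed must be a non-negative integer", call. = FALSE)
  }
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  sites <- cleavage_sites(p, rule)
  k <- length(sites)

  frag <- function(start, len, missed, full_length) {
    seq <- .wrap_substring(chars, start, len)
    m <- .fragment_mass(seq, p$cys_state)
    data.frame(sequence = seq, start = start, length = len, missed = missed,
               full_length = full_length, n_cys = .count_char(seq, "C"),
               neutral_mass = m, mz1 = mz(m, 1L), stringsAsFactors = FALSE)
  }

  rows <- list()
  if (p$topology == "cyclic") {
    if (k > 0L) {
      for (a in seq_len(k)) {
        for (b in seq_len(k)) {
          missed <- (b - a - 1L) %% k
          if (a == b) missed <- k - 1L   # full-length single-cut product
          full_length <- a == b
          if (!full_length && missed > max_missed) next
          start <- (sites[a] %% n) + 1L
          len <- if (full_length) n else ((sites[b] - sites[a] - 1L) %% n) + 1L
          rows[[length(rows) + 1L]] <- frag(start, len, missed, full_length)
        }
      }
    }
  } else {
    bounds <- c(0L, sites, n)
    nb <- length(bounds)
    for (i in seq_len(nb - 1L)) {
      for (j in (i + 1L):nb) {
        missed <- j - i - 1L
        if (missed > max_missed) next
        start <- bounds[i] + 1L
        len <- bounds[j] - bounds[i]
        rows[[length(rows) + 1L]] <- frag(start, len, missed,
                                          full_length = (len == n))
      }
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), start = integer(0),
               length = integer(0), missed = integer(0),
               full_length = logical(0), n_cys = integer(0),
               neutral_mass = numeric(0), mz1 = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parent") <- p
  attr(out, "rule") <- rule
  class(out) <- c("digest_fragments", "data.frame")
  out
}

#' Assign observed peaks to theoretical digest fragments
#'
#' Each observed peak is annotated with the best (nearest) theoretical
#' fragment whose singly protonated m/z lies within tolerance, or left
#' unassigned.  One fragment may be assigned to several peaks only across
#' charge states; in this z = 1 context a fragment is assigned to at most
#' one peak (the closest).
#'
#' @param fragments A `"digest_fragments"` table from [digest_peptide()].
#' @param observed A [peak_list()] of observed singly charged signals.
#' @param tolerance Matching tolerance (default 0.2).
#' @param tolerance_mode `"dalton"` or `"ppm"`.
#' @return A data frame with one row per observed peak: `mz`, `intensity`,
#'   `sequence` (NA when unassigned), `theoretical_mz1`, `error` in the
#'   active tolerance unit, `missed`.
#' @export
match_fragment_table <- function(fragments, observed, tolerance = 0.2,
                                 tolerance_mode = c("dalton", "ppm")) {
  tolerance_mode <- match.arg(tolerance_mode)
  stopifnot(is.data.frame(fragments))
  observed <- .as_peak_list(observed, arg = "observed")
  params <- screen_params(tolerance_mode, tolerance)
  np <- nrow(observed)
  out <- data.frame(mz = observed$mz, intensity = observed$intensity,
                    sequence = rep(NA_character_, np),
                    theoretical_mz1 = rep(NA_real_, np),
                    error = rep(NA_real_, np),
                    missed = rep(NA_integer_, np),
                    stringsAsFactors = FALSE)
  if (!np || !nrow(fragments)) return(out)
  taken <- logical(nrow(fragments))
  # peaks in ascending |best error| order so the closest peak claims a
  # fragment first
  pick <- function(i) {
    d <- abs(observed$mz[i] - fragments$mz1)
    d[taken] <- Inf
    j <- which.min(d)
    tol <- .tol_abs(fragments$mz1[j], params)
    if (d[j] <= tol) j else NA_integer_
  }
  prelim <- vapply(seq_len(nrow(observed)), function(i) {
    min(abs(observed$mz[i] - fragments$mz1))
  }, 0)
  for (i in order(prelim)) {
    j <- pick(i)
    if (is.na(j)) next
    taken[j] <- TRUE
    out$sequence[i] <- fragments$sequence[j]
    out$theoretical_mz1[i] <- fragments$mz1[j]
    out$error[i] <- .tol_dev(observed$mz[i], fragments$mz1[j], params)
    out$missed[i] <- fragments$missed[j]
  }
  out
}
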