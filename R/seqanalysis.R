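# Cyclotide sequence analytics: cystine-loop decomposition,
# Moebius/bracelet classification, identity-scored homology ranking, and
# frequency matrices for sequence logos.

#' Decompose a six-cysteine cyclic sequence into intercysteine loops
#'
#' Loop `i` is the stretch strictly between Cys `i` and Cys `i+1` (roman
#' numerals I-VI in the field's convention); loop 6 wraps from Cys VI back
#' to Cys I and contains the native ligation site.  The sequence as written
#' is expected to begin immediately after the ligation site, i.e. inside
#' loop 6, so the residues before the first Cys are the tail of loop 6.
#'
#' Because the backbone is a circle, the numbering needs an anchor that
#' does not depend on where the sequence happens to be written: when the
#' peptide carries exactly one Glu (the conserved loop-1 glutamate that
#' makes GluC ring opening single-cut), Cys I is chosen so that loop 1
#' contains that Glu, making the decomposition rotation-invariant.
#' Otherwise the first written cysteine is Cys I and the wrap is loop 6.
#'
#' @param cyclic_sequence Sequence of the cyclic peptide as written, with
#'   exactly six cysteines.
#' @return A list of class `"loop_decomposition"`: `sequence`,
#'   `cys_positions` (six 1-based indices), `loops` (character vector
#'   `loop1`..`loop6`).
#' @examples
#' loop_decompose("GVIPCGESCVFIPCISAAIGCSCKNKVCYRD")$loops
#' @export
loop_decompose <- function(cyclic_sequence) {
  cyclic_sequence <- .check_sequence(cyclic_sequence)
  chars <- strsplit(cyclic_sequence, "", fixed = TRUE)[[1L]]
  cys <- which(chars == "C")
  if (length(cys) != 6L) {
    stop(sprintf("expected exactly 6 cysteines, found %d", length(cys)),
         call. = FALSE)
  }
  n <- length(chars)
  # the six inter-cysteine gaps in cyclic order; gap i runs from the
  # residue after the i-th written Cys to the one before the next
  # (wrapping after the sixth)
  gaps <- character(6L)
  for (i in 1:6) {
    from <- cys[i] + 1L
    to <- if (i < 6L) cys[i + 1L] - 1L else cys[1L] - 1L + n
    idx <- if (from > to) integer(0) else ((from:to - 1L) %% n) + 1L
    gaps[i] <- paste(chars[idx], collapse = "")
  }
  # rotation-invariant anchor: loop 1 is the gap holding the single Glu
  anchor <- 1L
  if (sum(chars == "E") == 1L) {
    holds_e <- grepl("E", gaps, fixed = TRUE)
    if (sum(holds_e) == 1L) anchor <- which(holds_e)
  }
  ord <- ((anchor - 1L + 0:5) %% 6L) + 1L
  loops <- gaps[ord]
  names(loops) <- paste0("loop", 1:6)
  structure(
    list(sequence = cyclic_sequence, cys_positions = cys[ord],
         loops = loops),
    class = "loop_decomposition"
  )
}

#' @export
print.loop_decomposition <- function(x, ...) {
  cat(sprintf("<loop_decomposition> %s\n  Cys at %s\n", x$sequence,
              paste(x$cys_positions, collapse = ", ")))
  for (i in 1:6) cat(sprintf("  loop%d: %s\n", i, x$loops[i]))
  invisible(x)
}

#' Classify a cyclotide as Moebius or bracelet
#'
#' The subfamilies are defined by the presence (Moebius) or absence
#' (bracelet) of a cis-Pro in intercysteine loop 5.  From sequence alone
#' only the presence of a proline in loop 5 is observable - cis/trans
#' geometry is not inferable - so the classification is a sequence-level
#' proxy and the result carries that caveat.
#'
#' @param d A [loop_decompose()] result, or a six-Cys cyclic sequence.
#' @return A character scalar `"moebius"` or `"bracelet"`, with attribute
#'   `caveat` noting the sequence-level proxy.
#' @examples
#' classify_subtype("GVIPCGESCVFIPCISAAIGCSCKNKVCYRD")  # bracelet
#' @export
classify_subtype <- function(d) {
  if (is.character(d)) d <- loop_decompose(d)
  stopifnot(inherits(d, "loop_decomposition"))
  subtype <- if (grepl("P", d$loops[["loop5"]], fixed = TRUE)) "moebius"
             else "bracelet"
  structure(subtype,
            caveat = paste("assigned from the presence of Pro in loop 5;",
                           "cis/trans geometry is not inferable from",
                           "sequence"))
}

#' Identity score of the best gap-free-penalty alignment
#'
#' The maximum number of identical aligned characters over all alignments
#' scored match = 1, mismatch = 0, gap = 0.  With no penalties this equals
#' the longest-common-subsequence (LCS) length, computed by dynamic
#' programming.  Because no cell score can be negative, the local
#' (Smith-Waterman) optimum coincides with the global one under this
#' scheme, so `mode` does not change the result.
#'
#' @param a,b Non-empty sequences.
#' @param mode `"global"` (default) or `"local"`; equivalent under this
#'   scoring, both accepted for interface compatibility.
#' @return Integer identity score, `0 <= score <= min(nchar(a), nchar(b))`.
#' @examples
#' identity_alignment_score("ACGT", "AGT")  # 3
#' @export
identity_alignment_score <- function(a, b, mode = c("global", "local")) {
  match.arg(mode)
  a <- .check_sequence(a, "a"); b <- .check_sequence(b, "b")
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  prev <- integer(length(y) + 1L)
  for (i in seq_along(x)) {
    cur <- integer(length(y) + 1L)
    match_i <- x[i] == y
    for (j in seq_along(y)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L else
        max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[length(y) + 1L]
}

#' Rank a sequence library by identity score against a query
#'
#' @param query Query sequence (scored as written; for a cyclic query the
#'   best score over all rotations is available via `rotations = TRUE`).
#' @param library Data frame with columns `id` and `sequence`, or a named
#'   character vector of sequences.
#' @param rotations Score the maximum over all cyclic rotations of the
#'   query (default `FALSE`: mature-domain strings are compared as
#'   written).
#' @return A data frame of class `"homology_hits"`, descending by `score`
#'   (ties broken by `id`): `id`, `sequence`, `score`, `normalized_score`
#'   (= score / min(length) in \[0, 1\]).
#' @export
rank_homologs <- function(query, library, rotations = FALSE) {
  query <- .check_sequence(query, "query")
  if (is.character(library)) {
    library <- data.frame(id = names(library), sequence = unname(library),
                          stringsAsFactors = FALSE)
  }
  if (!is.data.frame(library) ||
      !all(c("id", "sequence") %in% names(library)) || !nrow(library)) {
    stop("library must be a non-empty data frame with 'id' and 'sequence'",
         call. = FALSE)
  }
  queries <- if (rotations) {
    n <- nchar(query)
    vapply(seq_len(n), function(k) {
      paste0(substr(query, k, n), substr(query, 1L, k - 1L))
    }, "")
  } else query
  score <- vapply(library$sequence, function(s) {
    max(vapply(queries, identity_alignment_score, 0L, b = s))
  }, 0L, USE.NAMES = FALSE)
  out <- data.frame(
    id = library$id, sequence = library$sequence, score = score,
    normalized_score = score / pmin(nchar(query), nchar(library$sequence)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("homology_hits", "data.frame")
  out
}

#' Per-column residue frequencies of an alignment
#'
#' The frequency of each residue among the non-gap characters of every
#' column (the matrix behind a frequency logo), with the per-column gap
#' fraction reported separately.
#'
#' @param aligned Character vector of equal-length aligned sequences; `-`
#'   is the gap character.
#' @return A list of class `"frequency_matrix"`: `freq` (residues x
#'   columns; each column sums to 1 over non-gap symbols, or is all zero
#'   for an all-gap column), `gap_fraction`, `n_sequences`.
#' @export
frequency_matrix <- function(aligned) {
  if (!is.character(aligned) || !length(aligned)) {
    stop("aligned must be a non-empty character vector", call. = FALSE)
  }
  aligned <- toupper(aligned)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  L <- lens[1L]
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  residues <- sort(setdiff(unique(as.vector(mat)), "-"))
  bad <- setdiff(residues, names(mass_constants()$residue_mass))
  if (length(bad)) {
    stop("non-residue characters in alignment: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  freq <- matrix(0, nrow = length(residues), ncol = L,
                 dimnames = list(residues, NULL))
  gap_fraction <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    gap_fraction[j] <- mean(col == "-")
    col <- col[col != "-"]
    if (length(col)) {
      tab <- table(col) / length(col)
      freq[names(tab), j] <- as.numeric(tab)
    }
  }
  structure(
    list(freq = freq, gap_fraction = gap_fraction,
         n_sequences = length(aligned)),
    class = "frequency_matrix"
  )
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("<frequency_matrix> %d sequences x %d columns (%d residues)\n",
              x$n_sequences, ncol(x$freq), nrow(x$freq)))
  invisible(x)
}
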