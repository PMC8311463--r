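# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA with peptide-state header keywords, peak-list CSV/TSV, MGF fragment
# spectra, and dose-response CSV tables.

#' Read peptides from FASTA with state keywords
#'
#' Headers are `>id key=value ...` with the optional keywords
#' `topology=cyclic|linear`, `cys_state=oxidized|reduced|cam`,
#' `disulfides=<int>` (defaults: linear, reduced, 0).  Unknown keywords are
#' rejected; lowercase sequences are uppercased with a message.
#'
#' @param path FASTA file path.
#' @return Named list of [peptide()] objects (names are the record ids).
#'   An empty file gives an empty list with a warning.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) {
    warning("no FASTA records in ", path, call. = FALSE)
    return(list())
  }
  out <- vector("list", length(set))
  ids <- character(length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    toks <- strsplit(trimws(header), "\\s+")[[1L]]
    ids[i] <- toks[1L]
    topology <- "linear"; cys_state <- "reduced"; disulfides <- 0L
    for (tok in toks[-1L]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) {
        stop(sprintf("malformed header token '%s' in record '%s'", tok,
                     ids[i]), call. = FALSE)
      }
      switch(kv[1L],
        topology = {
          topology <- match.arg(kv[2L], c("cyclic", "linear"))
        },
        cys_state = {
          cys_state <- switch(kv[2L],
            oxidized = "oxidized", reduced = "reduced",
            cam = "carbamidomethylated",
            stop(sprintf("unknown cys_state '%s' in record '%s'", kv[2L],
                         ids[i]), call. = FALSE))
        },
        disulfides = {
          disulfides <- suppressWarnings(as.integer(kv[2L]))
          if (is.na(disulfides)) {
            stop(sprintf("non-integer disulfides '%s' in record '%s'",
                         kv[2L], ids[i]), call. = FALSE)
          }
        },
        stop(sprintf("unknown header keyword '%s' in record '%s'", kv[1L],
                     ids[i]), call. = FALSE)
      )
    }
    seq <- as.character(set[[i]])
    if (grepl("[a-z]", seq)) {
      message("record '", ids[i], "': lowercase sequence uppercased")
      seq <- toupper(seq)
    }
    out[[i]] <- peptide(seq, topology = topology, cys_state = cys_state,
                        n_disulfides = disulfides)
  }
  names(out) <- ids
  out
}

#' Write peptides to FASTA with state keywords
#'
#' The inverse of [read_fasta()]: headers carry the topology, cysteine
#' state and disulfide count, so a written file round-trips identically.
#'
#' @param peptides Named list of [peptide()]s (names become record ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path) {
  stopifnot(is.list(peptides), length(names(peptides)) == length(peptides))
  lines <- character(0)
  for (i in seq_along(peptides)) {
    p <- peptides[[i]]
    stopifnot(inherits(p, "peptide"))
    state <- switch(p$cys_state, carbamidomethylated = "cam", p$cys_state)
    lines <- c(lines,
               sprintf(">%s topology=%s cys_state=%s disulfides=%d",
                       names(peptides)[i], p$topology, state,
                       p$n_disulfides),
               p$sequence)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a peak list from CSV/TSV
#'
#' Expects a header line `mz,intensity` (or tab-separated); `intensity` is
#' optional and defaults to 1.  Lines starting with `#` are comments.
#'
#' @param path File path.
#' @param label Optional derivatization label attached to the result.
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, label = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(peak_list(numeric(0), label = label))
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"mz" %in% names(df)) {
    stop("peak list must have an 'mz' column: ", path, call. = FALSE)
  }
  if (!is.numeric(df$mz)) {
    stop("non-numeric m/z values in ", path, call. = FALSE)
  }
  if ("intensity" %in% names(df) && !is.numeric(df$intensity)) {
    stop("non-numeric intensity values in ", path, call. = FALSE)
  }
  peak_list(df$mz, if ("intensity" %in% names(df)) df$intensity else NULL,
            label = label)
}

#' Write a peak list to CSV
#'
#' @param x A [peak_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  x <- .as_peak_list(x)
  lab <- attr(x, "label")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(lab)) writeLines(sprintf("# label=%s", lab), con)
  writeLines("mz,intensity", con)
  if (nrow(x)) {
    writeLines(sprintf("%.6f,%.6g", x$mz, x$intensity), con)
  }
  invisible(path)
}

#' Read MS/MS spectra from an MGF (Mascot generic format) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` and
#' `CHARGE` headers and centroided peak lines.  Spectra with a charge
#' other than `1+` are rejected: the MALDI post-source-decay context of
#' this package is singly charged.
#'
#' @param path MGF file path.
#' @return A list of spectra; each is a list with `title`, `pepmass`,
#'   `charge`, and `peaks` (a [peak_list()]).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- NA_character_; pepmass <- NA_real_; charge <- 1L
      mzs <- numeric(0); ints <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                         "\\s+")[[1L]][1L])
        } else if (startsWith(ln, "CHARGE=")) {
          ch <- sub("^CHARGE=", "", ln)
          if (!ch %in% c("1+", "1")) {
            stop(sprintf(
              "spectrum '%s' has CHARGE=%s; only singly charged spectra are supported",
              title, ch), call. = FALSE)
          }
        } else if (nzchar(ln) && !grepl("=", ln, fixed = TRUE)) {
          parts <- as.numeric(strsplit(ln, "\\s+")[[1L]])
          if (any(is.na(parts))) {
            stop("non-numeric peak line in ", path, ": '", ln, "'",
                 call. = FALSE)
          }
          mzs <- c(mzs, parts[1L])
          ints <- c(ints, if (length(parts) > 1L) parts[2L] else 1)
        }
        i <- i + 1L
      }
      spectra[[length(spectra) + 1L]] <- list(
        title = title, pepmass = pepmass, charge = charge,
        peaks = peak_list(mzs, ints, label = "msms"))
    }
    i <- i + 1L
  }
  spectra
}

#' Write MS/MS spectra to MGF
#'
#' @param spectra A list as returned by [read_mgf()], or a single spectrum
#'   list with `title`, `pepmass` and `peaks`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (!is.null(spectra$peaks)) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$title) && !is.na(sp$title)) {
      writeLines(paste0("TITLE=", sp$title), con)
    }
    if (!is.null(sp$pepmass) && !is.na(sp$pepmass)) {
      writeLines(sprintf("PEPMASS=%.6f", sp$pepmass), con)
    }
    writeLines("CHARGE=1+", con)
    pk <- .as_peak_list(sp$peaks)
    if (nrow(pk)) writeLines(sprintf("%.6f %.6g", pk$mz, pk$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a dose-response CSV table
#'
#' Expects columns `concentration`, `unit`, `response` and optionally
#' `replicate`.  All rows must share one concentration unit; mixing units
#' in a single table is rejected.
#'
#' @param path CSV file path.
#' @return A data frame with the validated columns; the unit is also
#'   recorded in the `"unit"` attribute.
#' @export
read_assay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration", "unit", "response")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("assay table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$concentration) || !is.numeric(df$response)) {
    stop("concentration and response must be numeric in ", path,
         call. = FALSE)
  }
  units <- unique(df$unit)
  if (length(units) != 1L) {
    stop("mixed concentration units in one table: ",
         paste(units, collapse = ", "), call. = FALSE)
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  attr(df, "unit") <- units
  df
}
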