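# Seeded generators emulating every input the pipeline consumes: cyclotide-
# like sequences, derivatization peak-list quadruples, b/y fragment spectra,
# and 4PL-shaped dose-response tables.  All generators are deterministic
# under a fixed seed and emit machine-readable ground truth.

# Residue alphabet for random loop positions: the composition loosely
# follows Violaceae cyclotide mature domains (small residues frequent, no
# Cys or Glu - those are placed by the architecture, so each product has
# exactly six Cys and a single GluC site).
.LOOP_ALPHABET <- c(G = 12, A = 6, S = 8, T = 6, V = 8, I = 7, L = 4,
                    P = 7, N = 7, D = 4, Q = 3, K = 6, R = 4, H = 2,
                    F = 4, Y = 4)

.sample_residues <- function(n) {
  if (n == 0L) return(character(0))
  sample(names(.LOOP_ALPHABET), n, replace = TRUE,
         prob = .LOOP_ALPHABET / sum(.LOOP_ALPHABET))
}

#' Generate cyclotide-like cyclic peptides with ground truth
#'
#' Products have the canonical architecture: six cysteines separated by six
#' intercysteine loops, a single Glu in loop 1 (so GluC opens the ring at
#' exactly one site), and an Asn/Asp ligation residue at the end of the
#' sequence as written (which starts immediately after the ligation site,
#' inside loop 6).  Sequences whose native oxidized \[M+H\]+ falls outside
#' `mass_window` are rejection-sampled away, mirroring the mass range in
#' which cyclotide screening is read out.
#'
#' @param n Number of peptides.
#' @param seed Optional integer seed (`set.seed` is called when given;
#'   otherwise the current RNG stream is used).
#' @param loop_lengths List of integer ranges for the six loop lengths.
#'   The defaults give 27-33 residue peptides, the cyclotide norm.
#' @param mass_window Native \[M+H\]+ acceptance window in Da (default
#'   2900-3550, the window in which cyclotide mass signals are screened).
#' @param min_separation_da Minimum native-mass separation between two
#'   generated peptides (default 6 Da; the peptides of a real screened
#'   extract sit 10 Da or more apart).  Peptides closer than the
#'   instrument resolves would appear as a single MALDI signal, so
#'   planting them as distinct entities would make recovery bookkeeping
#'   ill-posed.  In addition, pairwise spacings within 0.3 Da of
#'   `k x 57.0215` or `k x 58.0293` (k = 1..5) are rejected: two analytes
#'   on that lattice produce derivatization ladders that alias onto each
#'   other under a wrong cysteine count, an ambiguity the shift-matching
#'   chemistry itself cannot resolve, so planting such pairs would make
#'   the ground truth ill-defined (the same well-posedness rule the decoy
#'   placement follows).
#' @return A list: `peptides` (list of cyclic, oxidized, 3-disulfide
#'   [peptide()]s) and `truth` (data frame: `id`, `sequence`, `length`,
#'   `native_mz`, `reduced_mz`, `alkylated_mz`, `linearized_mz` - the
#'   exact theoretical singly protonated masses of the four derivatization
#'   states).
#' @export
generate_cyclotide_like <- function(n = 20L, seed = NULL,
                                    loop_lengths = list(loop1 = 3L,
                                                        loop2 = 3:4,
                                                        loop3 = 4:6,
                                                        loop4 = 1L,
                                                        loop5 = 4:5,
                                                        loop6 = 6:8),
                                    mass_window = c(2900, 3550),
                                    min_separation_da = 6) {
  if (!is.null(seed)) set.seed(seed)
  need <- paste0("loop", 1:6)
  if (!all(need %in% names(loop_lengths))) {
    stop("loop_lengths must name loop1..loop6", call. = FALSE)
  }
  if (any(vapply(loop_lengths[need], min, 0) < c(1, 0, 0, 0, 0, 1))) {
    stop("loop1 needs length >= 1 (it holds the Glu) and loop6 >= 1 ",
         "(it holds the ligation residue)", call. = FALSE)
  }
  cst <- mass_constants()
  # native spacings that keep recovery well-posed: resolved signals, off
  # the reduction/carbamidomethylation aliasing lattice
  spacing_ok <- function(m, prev) {
    if (!length(prev)) return(TRUE)
    d <- abs(m - prev)
    if (min(d) < min_separation_da) return(FALSE)
    for (k in 1:5) {
      if (any(abs(d - k * cst$cam_delta) < 0.3) ||
          any(abs(d - k * cst$alkylation_from_native_per_cys) < 0.3)) {
        return(FALSE)
      }
    }
    TRUE
  }
  peptides <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in seq_len(1000L)) {
      len <- vapply(loop_lengths[need], function(r) {
        if (length(r) == 1L) as.integer(r) else sample(r, 1L)
      }, 0L)
      # loop 1 with one Glu at a random position
      l1 <- .sample_residues(len[1L] - 1L)
      epos <- sample.int(len[1L], 1L)
      l1 <- append(l1, "E", after = epos - 1L)
      # loop 6 split around the ligation Asn/Asp (its last residue);
      # the written sequence starts right after the ligation site
      tail_len <- sample.int(len[6L], 1L) - 1L
      head6 <- c(.sample_residues(len[6L] - tail_len - 1L),
                 sample(c("N", "D"), 1L))
      tail6 <- .sample_residues(tail_len)
      written <- paste(c(tail6,
                         "C", l1,
                         "C", .sample_residues(len[2L]),
                         "C", .sample_residues(len[3L]),
                         "C", .sample_residues(len[4L]),
                         "C", .sample_residues(len[5L]),
                         "C", head6), collapse = "")
      p <- peptide(written, topology = "cyclic", cys_state = "oxidized",
                   n_disulfides = 3L)
      native_mz <- mz(peptide_neutral_mass(p), 1L)
      prev <- vapply(rows[!vapply(rows, is.null, TRUE)],
                     function(r) r$native_mz, 0)
      if (native_mz >= mass_window[1L] && native_mz <= mass_window[2L] &&
          spacing_ok(native_mz, prev)) break
      p <- NULL
    }
    if (is.null(p)) {
      stop("could not satisfy the mass window under these loop ranges",
           call. = FALSE)
    }
    reduced_mz <- native_mz + derivatization_delta(6L, "reduce")
    alkylated_mz <- native_mz +
      derivatization_delta(6L, "alkylate_from_native")
    peptides[[i]] <- p
    rows[[i]] <- data.frame(
      id = sprintf("syn%03d", i), sequence = p$sequence,
      length = nchar(p$sequence), native_mz = native_mz,
      reduced_mz = reduced_mz, alkylated_mz = alkylated_mz,
      linearized_mz = alkylated_mz + cst$ring_open_delta,
      stringsAsFactors = FALSE
    )
  }
  list(peptides = peptides, truth = do.call(rbind, rows))
}

# uniform decoy m/z values over `window`, each at least `excl_ppm` away
# from every value in `avoid`
.decoy_mz <- function(n, window, avoid, excl_ppm) {
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < 1000L * max(n, 1L)) {
    x <- stats::runif(1L, window[1L], window[2L])
    if (!length(avoid) ||
        min(abs(x - avoid)) > excl_ppm * 1e-6 * x) {
      out <- c(out, x)
      avoid <- c(avoid, x)
    }
    tries <- tries + 1L
  }
  out
}

#' Simulate the four derivatization peak lists for a set of peptides
#'
#' Emits native, reduced, alkylated and ring-opened (linearized) peak lists
#' with the exact chemical shifts of the screening workflow.  Measurement
#' error is modelled on each observed mass *shift*: every derivative peak
#' carries an independent Gaussian ppm-scale error relative to the peak it
#' chemically derives from (the native anchor for the reduced peak, and so
#' on along the chain), which is the quantity the series-matching step
#' evaluates.  Decoy peaks are drawn uniformly over each list's mass window
#' but rejected within `decoy_exclusion_ppm` of any true peak, so
#' false-positive measurements on the output are well-posed.
#'
#' @param peptides List of six-Cys cyclic [peptide()]s, or the list
#'   returned by [generate_cyclotide_like()].
#' @param ppm_noise_sd SD of the ppm-scale error on each observed shift
#'   (default 10 ppm).
#' @param decoys_per_list Number of decoy peaks added to each list.
#' @param dropout_prob Per-peak dropout probabilities, a named vector over
#'   `reduced`, `alkylated`, `linearized` (native peaks anchor the series
#'   bookkeeping and are always kept); a single number is recycled.
#' @param decoy_exclusion_ppm Minimum distance of a decoy from any true
#'   peak (default 75 ppm, three times the usual matching tolerance).
#' @param seed Optional integer seed.
#' @return A list with the four [peak_list()]s (`native`, `reduced`,
#'   `alkylated`, `linearized`) and `truth`: one row per peptide with the
#'   observed m/z of each planted peak (`NA` where dropped) and the exact
#'   theoretical values.
#' @export
simulate_derivatization_peaklists <- function(peptides,
                                              ppm_noise_sd = 10,
                                              decoys_per_list = 5L,
                                              dropout_prob = 0,
                                              decoy_exclusion_ppm = 75,
                                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.list(peptides) && !is.null(peptides$peptides)) {
    peptides <- peptides$peptides
  }
  stopifnot(length(peptides) > 0L,
            all(vapply(peptides, inherits, TRUE, "peptide")))
  if (length(dropout_prob) == 1L && is.null(names(dropout_prob))) {
    dropout_prob <- c(reduced = dropout_prob, alkylated = dropout_prob,
                      linearized = dropout_prob)
  }
  drop_p <- function(key) {
    p <- dropout_prob[key]
    if (is.na(p)) 0 else as.numeric(p)
  }
  cst <- mass_constants()
  jitter1 <- function(x) x * (1 + stats::rnorm(1L, 0, ppm_noise_sd * 1e-6))

  n <- length(peptides)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- peptides[[i]]
    ncys <- .count_char(p$sequence, "C")
    nat_true <- mz(peptide_neutral_mass(p), 1L)
    red_true <- nat_true + derivatization_delta(ncys, "reduce")
    alk_true <- nat_true + derivatization_delta(ncys, "alkylate_from_native")
    lin_true <- alk_true + cst$ring_open_delta

    nat_obs <- jitter1(nat_true)
    red_obs <- jitter1(nat_obs + derivatization_delta(ncys, "reduce"))
    alk_obs <- jitter1(red_obs + ncys * cst$cam_delta)
    lin_obs <- jitter1(alk_obs + cst$ring_open_delta)
    if (stats::runif(1L) < drop_p("reduced")) red_obs <- NA_real_
    if (stats::runif(1L) < drop_p("alkylated")) alk_obs <- NA_real_
    if (stats::runif(1L) < drop_p("linearized")) lin_obs <- NA_real_

    rows[[i]] <- data.frame(
      id = sprintf("pep%03d", i), sequence = p$sequence, n_cys = ncys,
      native_mz = nat_obs, reduced_mz = red_obs, alkylated_mz = alk_obs,
      linearized_mz = lin_obs, native_mz_true = nat_true,
      reduced_mz_true = red_true, alkylated_mz_true = alk_true,
      linearized_mz_true = lin_true, stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, rows)

  build <- function(obs, true, label) {
    window <- range(true) + c(-5, 5)
    decoys <- .decoy_mz(decoys_per_list, window, true, decoy_exclusion_ppm)
    peak_list(c(obs[!is.na(obs)], decoys), label = label)
  }
  list(
    native = build(truth$native_mz, truth$native_mz_true, "native"),
    reduced = build(truth$reduced_mz, truth$reduced_mz_true, "reduced"),
    alkylated = build(truth$alkylated_mz, truth$alkylated_mz_true,
                      "alkylated"),
    linearized = build(truth$linearized_mz, truth$linearized_mz_true,
                       "linearized"),
    truth = truth
  )
}

#' Simulate an MS/MS fragment spectrum for a linear peptide
#'
#' Each base b/y ion is emitted with probability `ion_prob`; each of its
#' -17/-18 loss variants independently with probability `loss_prob`.
#' Emitted peaks carry additive Gaussian m/z jitter, and uniform noise
#' peaks are sprinkled over the fragment range.
#'
#' @param linear_sequence Linear sequence (length >= 2).
#' @param cys_state Cysteine state (default carbamidomethylated).
#' @param ion_prob Sampling probability of each base ion.
#' @param loss_prob Sampling probability of each loss variant.
#' @param mz_sd Additive m/z jitter SD in Da (default 0.02).
#' @param n_noise_peaks Number of uniform noise peaks (default 10).
#' @param seed Optional integer seed.
#' @return A list: `spectrum` (a [peak_list()]) and `truth` (data frame of
#'   emitted ions: `series`, `index`, `loss`, `mz1` theoretical,
#'   `mz_observed`).
#' @export
simulate_msms <- function(linear_sequence,
                          cys_state = c("carbamidomethylated", "reduced"),
                          ion_prob = 0.8, loss_prob = 0.2, mz_sd = 0.02,
                          n_noise_peaks = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cys_state <- match.arg(cys_state)
  ions <- theoretical_ions(linear_sequence, cys_state, losses = TRUE)
  base <- ions$loss == "none"
  keep <- logical(nrow(ions))
  keep[base] <- stats::runif(sum(base)) < ion_prob
  keep[!base] <- stats::runif(sum(!base)) < loss_prob
  truth <- ions[keep, , drop = FALSE]
  truth$mz_observed <- truth$mz1 + stats::rnorm(nrow(truth), 0, mz_sd)
  noise <- if (n_noise_peaks > 0L) {
    stats::runif(n_noise_peaks, 100,
                 max(c(ions$mz1, 200)))
  } else numeric(0)
  all_mz <- c(truth$mz_observed, noise)
  all_int <- c(stats::runif(nrow(truth), 20, 100),
               stats::runif(length(noise), 1, 10))
  ok <- all_mz > 0
  spec <- if (any(ok)) peak_list(all_mz[ok], all_int[ok], label = "msms")
          else peak_list(numeric(0), label = "msms")
  rownames(truth) <- NULL
  list(spectrum = spec, truth = truth)
}

#' Simulate a 4PL-shaped dose-response table
#'
#' Responses follow the four-parameter logistic model with multiplicative
#' Gaussian noise at a stated coefficient of variation, the error behavior
#' of plate-reader assays.
#'
#' @param ic50 True half-maximal concentration (default 4.4, in `unit`).
#' @param hill True Hill slope (default -2.8; negative for inhibition with
#'   the response expressed as remaining activity).
#' @param top,bottom True asymptotes (default 100 and 0 percent).
#' @param doses Concentration grid; default 8 log-spaced doses over
#'   0.1-60, the concentration range over which purified peptide
#'   inhibitors are titrated.
#' @param replicates Replicates per dose (default 5).
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param unit Concentration unit string echoed into the table (default
#'   `"uM"`).
#' @param seed Optional integer seed.
#' @return A list: `data` (data frame `concentration`, `unit`, `response`,
#'   `replicate`) and `truth` (list of the generating parameters).
#' @export
simulate_dose_response <- function(ic50 = 4.4, hill = -2.8, top = 100,
                                   bottom = 0, doses = NULL,
                                   replicates = 5L, noise_cv = 0.05,
                                   unit = "uM", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(doses)) {
    doses <- 10^seq(log10(0.1), log10(60), length.out = 8L)
  }
  stopifnot(all(doses > 0), replicates >= 1L, noise_cv >= 0)
  x <- rep(log10(doses), each = replicates)
  mu <- fourpl(x, bottom, top, log10(ic50), hill)
  y <- mu * (1 + stats::rnorm(length(mu), 0, noise_cv))
  list(
    data = data.frame(
      concentration = rep(doses, each = replicates), unit = unit,
      response = y, replicate = rep(seq_len(replicates), length(doses)),
      stringsAsFactors = FALSE
    ),
    truth = list(ic50 = ic50, log_ic50 = log10(ic50), hill = hill,
                 top = top, bottom = bottom, noise_cv = noise_cv,
                 doses = doses, replicates = replicates, unit = unit)
  )
}
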