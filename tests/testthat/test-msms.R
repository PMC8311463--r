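# b/y fragment-ion ladders, spectrum annotation, evidence combination and
# Ile/Leu resolution.

test_that("b/y ladders satisfy the complementarity identity", {
  set.seed(71)
  for (rep in 1:10) {
    s <- random_sequence(sample(5:25, 1))
    for (state in c("reduced", "carbamidomethylated")) {
      n <- nchar(s)
      ions <- theoretical_ions(s, state, losses = FALSE)
      b <- ions$mz1[ions$series == "b"]
      y <- ions$mz1[ions$series == "y"]
      M <- peptide_neutral_mass(
        if (state == "carbamidomethylated")
          peptide(s, cys_state = "carbamidomethylated")
        else peptide(s))
      for (i in seq_len(n - 1L)) {
        expect_equal(b[i] + y[n - i], M + 2 * 1.007276, tolerance = 1e-9)
      }
    }
  }
})

test_that("ion ladders have the right size and reference values", {
  # y1 of "GA": A + water + proton
  ions <- theoretical_ions("GA", "reduced", losses = FALSE)
  expect_equal(ions$mz1[ions$series == "y" & ions$index == 1],
               71.03711 + 18.010565 + 1.007276, tolerance = 1e-5)
  lad <- theoretical_ions("SCVFIPCISAAIGCSCKNKVCYRDGVIPCGE",
                          "carbamidomethylated", losses = TRUE)
  expect_equal(nrow(lad), 2L * 30L * 3L)   # 2 series x (n-1) x 3 loss states
  expect_equal(sort(unique(lad$loss)), c("H2O", "NH3", "none"))
  # loss variants sit exactly -17.026549 / -18.010565 below the base ion
  b5 <- lad[lad$series == "b" & lad$index == 5, ]
  expect_equal(b5$mz1[b5$loss == "NH3"], b5$mz1[b5$loss == "none"] -
                 17.026549, tolerance = 1e-9)
  expect_error(theoretical_ions(peptide("GAG", "cyclic")), "linearize")
  expect_error(theoretical_ions("G"), "at least 2")
})

test_that("annotation covers complete ladders and either series suffices", {
  s <- "GVIPCGESCVFIPCK"
  ions <- theoretical_ions(s, "carbamidomethylated", losses = FALSE)
  full <- peak_list(sort(ions$mz1))
  a <- annotate_spectrum(full, s, tolerance = 0.1, losses = FALSE)
  expect_equal(a$coverage, 1.0)
  # y-series alone achieves full coverage
  yonly <- peak_list(sort(ions$mz1[ions$series == "y"]))
  ay <- annotate_spectrum(yonly, s, tolerance = 0.1, losses = FALSE)
  expect_equal(ay$coverage, 1.0)
  # empty spectrum: coverage 0, no error
  a0 <- annotate_spectrum(peak_list(numeric(0)), s)
  expect_equal(a0$coverage, 0)
  expect_equal(a0$unsupported_positions, seq_len(nchar(s)))
})

test_that("removing the ions bounding a position leaves it unsupported", {
  s <- "GVIPAGESAVFIPAK"   # 15-mer, no Cys
  n <- nchar(s)
  ions <- theoretical_ions(s, "reduced", losses = FALSE)
  # drop every ion with a boundary at 2..4: b2..b4 and y11..y13
  keep <- !((ions$series == "b" & ions$index %in% 2:4) |
              (ions$series == "y" & ions$index %in% (n - 4):(n - 2)))
  spec <- peak_list(sort(ions$mz1[keep]))
  a <- annotate_spectrum(spec, s, tolerance = 0.1, losses = FALSE)
  # boundaries 2,3,4 gone; boundaries 1 and 5 still support residues 1-2, 5-6
  expect_equal(a$unsupported_positions, 3:4)
  expect_equal(a$coverage, (n - 2) / n)
})

test_that("annotation coverage is monotone in tolerance", {
  set.seed(72)
  s <- random_sequence(18)
  sim <- simulate_msms(s, ion_prob = 0.6, loss_prob = 0.1, mz_sd = 0.1,
                       n_noise_peaks = 5, seed = 73)
  covs <- vapply(c(0.05, 0.15, 0.3, 0.6), function(tol) {
    annotate_spectrum(sim$spectrum, s, tolerance = tol)$coverage
  }, 0)
  expect_true(all(diff(covs) >= 0))
})

test_that("evidence from differently opened linear forms combines", {
  # two half-coverage annotations with complementary gaps close the circle
  parent_len <- 12L
  mk <- function(seq, support) {
    structure(list(sequence = seq, matched_ions = NULL,
                   residue_support = support, coverage = mean(support),
                   unsupported_positions = which(!support)),
              class = "annotation_result")
  }
  s1 <- rep(c(TRUE, FALSE), each = 6)
  s2 <- rep(c(FALSE, TRUE), each = 6)
  seqs <- strrep("A", parent_len)
  comb <- combine_evidence(list(mk(seqs, s1), mk(seqs, s2)),
                           starts = c(1L, 1L), parent_length = parent_len)
  expect_equal(comb$coverage, 1.0)
  # an opening offset maps support back to cyclic coordinates
  comb2 <- combine_evidence(list(mk(seqs, s1), mk(seqs, s1)),
                            starts = c(1L, 7L), parent_length = parent_len)
  expect_equal(comb2$coverage, 1.0)
  # single input is the identity
  comb3 <- combine_evidence(list(mk(seqs, s1)), starts = 1L,
                            parent_length = parent_len)
  expect_equal(comb3$support, s1)
  expect_error(combine_evidence(list(mk(strrep("A", 10), rep(TRUE, 10))),
                                starts = 1L, parent_length = 12L),
               "full parent length")
})

test_that("MS/MS spectra of full-length ring-opened digests annotate back", {
  cam1 <- alca_peptides("carbamidomethylated")$alca1
  lin <- digest_peptide(cam1, gluc_rule())$sequence
  sim <- simulate_msms(lin, ion_prob = 1, loss_prob = 0, mz_sd = 0,
                       n_noise_peaks = 0, seed = 74)
  a <- annotate_spectrum(sim$spectrum, lin, tolerance = 0.3)
  expect_equal(a$coverage, 1.0)
})

test_that("chymotryptic boundaries resolve Ile/Leu as in the alca peptides", {
  # alca 2: written positions 2, 11, 14 are Ile, 18 is Leu
  cand2 <- "GJPCGESCVFJPCJSGVJGCSCSNKVCYRN"
  obs2 <- peak_list(c(858.4754, 2073.9225, 1395.6144))
  r2 <- resolve_ile_leu(cand2, obs2, tolerance = 0.2)
  calls <- stats::setNames(r2$resolved$call, r2$resolved$position)
  expect_equal(calls[["18"]], "L")
  expect_equal(calls[["2"]], "I")
  expect_equal(calls[["11"]], "I")
  expect_equal(calls[["14"]], "I")
  expect_true(all(r2$resolved$evidence == "chymotryptic_cleavage"))
  expect_equal(r2$sequence, "GIPCGESCVFIPCISGVLGCSCSNKVCYRN")
  # alca 1: positions 3, 12, 15, 19 all Ile (never a chymotryptic boundary)
  cand1 <- "GVJPCGESCVFJPCJSAAJGCSCKNKVCYRD"
  obs1 <- peak_list(c(2100.9697, 1495.6668))
  r1 <- resolve_ile_leu(cand1, obs1, tolerance = 0.2)
  expect_true(all(r1$resolved$call == "I"))
  expect_equal(r1$sequence, "GVIPCGESCVFIPCISAAIGCSCKNKVCYRD")
})

test_that("Ile/Leu calls require supporting fragments", {
  cand <- "GJPCGESCVFJPCJSGVJGCSCSNKVCYRN"
  # no observed fragments: everything stays unresolved
  r <- resolve_ile_leu(cand, peak_list(numeric(0)))
  expect_true(all(r$resolved$call == "J"))
  expect_true(all(r$resolved$evidence == "none"))
  # no J positions: input returned unchanged
  r0 <- resolve_ile_leu("GIPCGESCVF", peak_list(1395.6144))
  expect_equal(r0$sequence, "GIPCGESCVF")
  expect_equal(nrow(r0$resolved), 0L)
})

test_that("a planted Leu is recovered from a complete chymotryptic set", {
  set.seed(75)
  g <- generate_cyclotide_like(n = 5, seed = 75)
  for (p in g$peptides) {
    s <- p$sequence
    il <- gregexpr("[IL]", s)[[1L]]
    if (il[1L] == -1L) next
    cam <- peptide(s, "cyclic", "carbamidomethylated")
    frags <- digest_peptide(cam, chymotrypsin_rule(), max_missed = 1)
    if (!nrow(frags)) next
    cand <- s
    for (pos in il) substr(cand, pos, pos) <- "J"
    res <- resolve_ile_leu(cand, peak_list(sort(unique(frags$mz1))),
                           tolerance = 0.05)
    truth <- strsplit(s, "")[[1L]][res$resolved$position]
    resolved <- res$resolved$call != "J"
    # no call may contradict the planted identity
    expect_true(all(res$resolved$call[resolved] == truth[resolved]))
  }
})
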