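# In-silico proteolysis of cyclic and linear peptides.

cam_alca <- alca_peptides("carbamidomethylated")

test_that("cleavage sites follow enzyme specificity on cyclic parents", {
  expect_equal(cleavage_sites(cam_alca$alca1, trypsin_rule()),
               c(24L, 26L, 30L))
  expect_equal(cleavage_sites(cam_alca$alca1, gluc_rule()), 7L)
  expect_equal(cleavage_sites(cam_alca$alca2, chymotrypsin_rule()),
               c(10L, 18L, 28L))
  expect_length(cleavage_sites(peptide("GAGAGA", "cyclic"), trypsin_rule()),
                0L)
  # trypsin is blocked by a following proline, wrapping across the join
  expect_equal(cleavage_sites(peptide("KPGGKA", "cyclic"), trypsin_rule()),
               5L)
  expect_equal(cleavage_sites(peptide("GGKAGR", "cyclic"), trypsin_rule()),
               c(3L, 6L))
  # linear parent: no cleavage after the C-terminal residue
  expect_equal(cleavage_sites(peptide("GGKAGR"), trypsin_rule()), 3L)
})

test_that("GluC opens a single-Glu cyclic peptide at exactly one point", {
  g <- digest_peptide(cam_alca$alca1, gluc_rule())
  expect_equal(nrow(g), 1L)
  expect_equal(g$sequence, "SCVFIPCISAAIGCSCKNKVCYRDGVIPCGE")
  expect_true(g$full_length)
  expect_equal(g$mz1, 3577.6187, tolerance = 1e-3)
  g2 <- digest_peptide(cam_alca$alca2, gluc_rule())
  expect_equal(g2$sequence, "SCVFIPCISGVLGCSCSNKVCYRNGIPCGE")
  expect_equal(g2$mz1, 3450.519, tolerance = 1e-3)
})

test_that("cyclic tryptic digest yields the observed fragment set", {
  tr <- digest_peptide(cam_alca$alca1, trypsin_rule(), max_missed = 2)
  expect_true(all(c("NK", "VCYR", "NKVCYR",
                    "DGVIPCGESCVFIPCISAAIGCSCK",
                    "DGVIPCGESCVFIPCISAAIGCSCKNKVCYR") %in% tr$sequence))
  # complete digest: as many fragments as sites
  expect_equal(sum(tr$missed == 0L), 3L)
  # reference masses (independently computed)
  m <- function(s) tr$mz1[match(s, tr$sequence)]
  expect_equal(m("VCYR"), 597.2813, tolerance = 1e-3)
  expect_equal(m("NKVCYR"), 839.4192, tolerance = 1e-3)
  expect_equal(m("DGVIPCGESCVFIPCISAAIGCSCKNKVCYR"), 3577.6187,
               tolerance = 1e-3)
  # the full-length single-cut forms are flagged even above max_missed
  tr1 <- digest_peptide(cam_alca$alca1, trypsin_rule(), max_missed = 0)
  expect_equal(sum(tr1$full_length), 3L)
  expect_true(all(tr1$missed[tr1$full_length] == 2L))
})

test_that("cyclic digestion conserves mass and is rotation invariant", {
  set.seed(61)
  g <- generate_cyclotide_like(n = 8, seed = 61)
  for (p in g$peptides) {
    cam <- peptide(p$sequence, "cyclic", "carbamidomethylated")
    for (rule in list(trypsin_rule(), chymotrypsin_rule())) {
      fr <- digest_peptide(cam, rule, max_missed = 0)
      k <- length(cleavage_sites(cam, rule))
      if (k == 0L) {
        expect_equal(nrow(fr), 0L)
        next
      }
      # for k >= 2 the missed-0 rows are the k complete fragments; for
      # k = 1 the single full-length product plays that role
      expect_equal(sum(fr$missed == 0L), k)
      expect_equal(sum(fr$neutral_mass[fr$missed == 0L]),
                   peptide_neutral_mass(cam) + k * 18.010565,
                   tolerance = 1e-6)
      # any rotation digests to the same fragment multiset
      n <- nchar(cam$sequence)
      r <- sample(n, 1)
      rot <- peptide(paste0(substr(cam$sequence, r, n),
                            substr(cam$sequence, 1, r - 1)),
                     "cyclic", "carbamidomethylated")
      fr_rot <- digest_peptide(rot, rule, max_missed = 0)
      expect_setequal(fr$sequence, fr_rot$sequence)
    }
  }
})

test_that("every complete fragment appears in some single-cut linear form", {
  cam <- cam_alca$alca1
  fr <- digest_peptide(cam, trypsin_rule(), max_missed = 0)
  complete <- fr$sequence[fr$missed == 0L & !fr$full_length]
  linear_forms <- fr$sequence[fr$full_length]
  for (s in complete) {
    in_some <- any(vapply(linear_forms, function(lf) {
      lin <- digest_peptide(peptide(lf, "linear", "carbamidomethylated"),
                            trypsin_rule(), max_missed = 0)
      s %in% lin$sequence
    }, TRUE))
    expect_true(in_some, label = paste("fragment", s, "found in a linear form"))
  }
})

test_that("cyclic parent with no sites yields nothing", {
  p <- peptide("GAGAGAGAG", "cyclic")
  expect_equal(nrow(digest_peptide(p, trypsin_rule())), 0L)
})

test_that("observed chymotryptic peaks are assigned to the right fragments", {
  ch2 <- digest_peptide(cam_alca$alca2, chymotrypsin_rule(), max_missed = 2)
  obs <- peak_list(c(858.5, 1234.5, 1395.6))
  tab <- match_fragment_table(ch2, obs, tolerance = 0.2)
  expect_equal(tab$sequence,
               c("IPCISGVL", "GCSCSNKVCY", "RNGIPCGESCVF"))
  # empty observed list gives an empty table
  tab0 <- match_fragment_table(ch2, peak_list(numeric(0)))
  expect_equal(nrow(tab0), 0L)
  # simulated observed peaks at U(-0.05, 0.05) Da noise all assign correctly
  set.seed(62)
  tr <- digest_peptide(cam_alca$alca1, trypsin_rule(), max_missed = 1)
  noisy <- sort(tr$mz1 + stats::runif(nrow(tr), -0.05, 0.05))
  tab2 <- match_fragment_table(tr, peak_list(noisy), tolerance = 0.2)
  expect_equal(sort(tab2$sequence), sort(tr$sequence))
})

test_that("linear digestion follows standard bookkeeping", {
  p <- peptide("GAKGGRAA", "linear", "reduced")
  fr <- digest_peptide(p, trypsin_rule(), max_missed = 1)
  expect_setequal(fr$sequence[fr$missed == 0L], c("GAK", "GGR", "AA"))
  expect_setequal(fr$sequence[fr$missed == 1L], c("GAKGGR", "GGRAA"))
  # fragment masses are linear-peptide masses
  expect_equal(fr$neutral_mass[fr$sequence == "AA"],
               2 * 71.037114 + 18.010565, tolerance = 1e-6)
})
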