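# Derivatization-series screening: chaining, cysteine-count inference,
# injectivity and classification.

test_that("a single published series row matches as a six-Cys cyclic peptide", {
  p <- screen_params("dalton", 0.2)
  res <- match_series(peak_list(2948.1, label = "native"),
                      peak_list(2954.1, label = "reduced"),
                      peak_list(3296.3, label = "alkylated"),
                      peak_list(3314.3, label = "linearized"), p)
  expect_equal(nrow(res), 1L)
  expect_equal(res$inferred_n_cys, 6L)
  expect_equal(res$classification, "six_cys_cyclic")
  expect_true(all(abs(c(res$dev_reduce, res$dev_alkylate,
                        res$dev_ring_open)) <= 0.2))
})

test_that("natives without companions yield no series; empty input is empty", {
  p <- screen_params("dalton", 0.2)
  res <- match_series(peak_list(3000.0, label = "native"),
                      peak_list(3200.0, label = "reduced"),
                      peak_list(3400.0, label = "alkylated"),
                      peak_list(3600.0, label = "linearized"), p)
  expect_equal(nrow(res), 0L)
  res0 <- match_series(peak_list(numeric(0), label = "native"),
                       peak_list(2954.1, label = "reduced"),
                       peak_list(3296.3, label = "alkylated"),
                       peak_list(3314.3, label = "linearized"), p)
  expect_equal(nrow(res0), 0L)
  rep0 <- screen_report(res0, p)
  expect_true(all(rep0$counts == 0L))
})

test_that("mislabeled peak lists are rejected", {
  p <- screen_params("dalton", 0.2)
  expect_error(
    match_series(peak_list(2948.1, label = "reduced"),
                 peak_list(2954.1, label = "reduced"),
                 peak_list(3296.3, label = "alkylated"),
                 peak_list(3314.3, label = "linearized"), p),
    "labelled")
})

test_that("noise-free synthetic data is recovered perfectly", {
  g <- generate_cyclotide_like(n = 25, seed = 21)
  sim <- simulate_derivatization_peaklists(g$peptides, ppm_noise_sd = 0,
                                           decoys_per_list = 0, seed = 22)
  res <- match_series(sim$native, sim$reduced, sim$alkylated,
                      sim$linearized, screen_params("ppm", 25))
  expect_equal(nrow(res), 25L)
  expect_true(all(res$classification == "six_cys_cyclic"))
  expect_true(all(res$inferred_n_cys == 6L))
  expect_setequal(round(res$native_mz, 6), round(sim$truth$native_mz, 6))
})

test_that("matching is monotone in tolerance and deterministic", {
  g <- generate_cyclotide_like(n = 30, seed = 31)
  sim <- simulate_derivatization_peaklists(g$peptides, ppm_noise_sd = 12,
                                           decoys_per_list = 8, seed = 32)
  counts <- vapply(c(5, 10, 25, 50), function(tol) {
    nrow(match_series(sim$native, sim$reduced, sim$alkylated,
                      sim$linearized, screen_params("ppm", tol)))
  }, 0L)
  expect_true(all(diff(counts) >= 0L))
  p <- screen_params("ppm", 25)
  r1 <- match_series(sim$native, sim$reduced, sim$alkylated,
                     sim$linearized, p)
  r2 <- match_series(sim$native, sim$reduced, sim$alkylated,
                     sim$linearized, p)
  expect_identical(r1, r2)
})

test_that("no companion peak is claimed by two series", {
  # two natives that would both chain onto one shared set of companions
  p <- screen_params("dalton", 0.3)
  nat <- peak_list(c(2948.0, 2948.2), label = "native")
  red <- peak_list(2954.147, label = "reduced")
  alk <- peak_list(3296.276, label = "alkylated")
  lin <- peak_list(3314.286, label = "linearized")
  res <- match_series(nat, red, alk, lin, p)
  expect_equal(nrow(res), 1L)   # only the closer native wins the chain
  g <- generate_cyclotide_like(n = 40, seed = 41)
  sim <- simulate_derivatization_peaklists(g$peptides, ppm_noise_sd = 10,
                                           decoys_per_list = 10, seed = 42)
  res2 <- match_series(sim$native, sim$reduced, sim$alkylated,
                       sim$linearized, screen_params("ppm", 25))
  expect_false(any(duplicated(res2$reduced_mz)))
  expect_false(any(duplicated(res2$alkylated_mz)))
  expect_false(any(duplicated(stats::na.omit(res2$linearized_mz))))
})

test_that("linearized dropout downgrades series to incomplete", {
  g <- generate_cyclotide_like(n = 50, seed = 51)
  sim <- simulate_derivatization_peaklists(
    g$peptides, ppm_noise_sd = 0, decoys_per_list = 0,
    dropout_prob = c(linearized = 0.1), seed = 52)
  res <- match_series(sim$native, sim$reduced, sim$alkylated,
                      sim$linearized, screen_params("ppm", 25))
  rep <- screen_report(res, screen_params("ppm", 25))
  # six_cys_cyclic + incomplete account for every planted peptide
  expect_equal(rep$counts[["six_cys_cyclic"]] + rep$counts[["incomplete"]],
               50L)
  n_dropped <- sum(is.na(sim$truth$linearized_mz))
  expect_equal(rep$counts[["incomplete"]], n_dropped)
  # total dropout: everything incomplete
  sim2 <- simulate_derivatization_peaklists(
    g$peptides, ppm_noise_sd = 0, decoys_per_list = 0,
    dropout_prob = c(linearized = 1), seed = 53)
  res2 <- match_series(sim2$native, sim2$reduced, sim2$alkylated,
                       sim2$linearized, screen_params("ppm", 25))
  expect_true(all(res2$classification == "incomplete"))
})

test_that("screen parameters are validated", {
  expect_error(screen_params("dalton", -1), "positive")
  expect_error(screen_params("ppm", 25, cys_candidates = integer(0)),
               "non-empty")
  p <- screen_params("ppm", 25)
  expect_error(match_series(peak_list(3000, label = "native"),
                            peak_list(3006, label = "reduced"),
                            peak_list(3348, label = "alkylated"),
                            NULL, p),
               "linearized")
})
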