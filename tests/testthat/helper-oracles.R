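# Independent reference implementations and small fixture builders used
# across the suite.

# exponential-time recursive LCS: the reference oracle for short strings
lcs_oracle <- function(a, b) {
  rec <- function(i, j) {
    if (i == 0L || j == 0L) return(0L)
    if (substr(a, i, i) == substr(b, j, j)) {
      1L + rec(i - 1L, j - 1L)
    } else {
      max(rec(i - 1L, j), rec(i, j - 1L))
    }
  }
  rec(nchar(a), nchar(b))
}

aa_letters <- function() names(mass_constants()$residue_mass)

random_sequence <- function(n, alphabet = aa_letters()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# the four published A. cauliflora derivatization columns as peak lists
table_peaklists <- function() {
  tab <- acauliflora_screen_table()
  list(
    native = peak_list(tab$native, label = "native"),
    reduced = peak_list(tab$reduced, label = "reduced"),
    alkylated = peak_list(tab$alkylated, label = "alkylated"),
    linearized = peak_list(tab$linearized, label = "linearized")
  )
}

# per-residue tally oracle for the 280 nm extinction coefficient
ec280_oracle <- function(sequence, n_cystine) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(vapply(chars, function(ch) {
    switch(ch, Y = 1490, W = 5500, 0)
  }, 0)) + 125 * n_cystine
}
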