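---
title: "Methods behind cyclopep: screening, digestion, annotation and curve fitting for cyclotides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind cyclopep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclopep)
```

Cyclotides are ~30-residue plant peptides with a head-to-tail cyclic
backbone and six conserved cysteines forming a cyclic cystine knot.  Their
discovery workflow is almost entirely mass-spectrometric: a candidate
signal in a plant extract is characterized by chemical derivatization
(disulfide reduction, S-carbamidomethylation, enzymatic ring opening),
sequenced by multi-enzyme proteolysis plus b/y-ion MS/MS, and its
bioactivity quantified by enzyme-inhibition curves.  `cyclopep` implements
that desk-side pipeline end to end.  This vignette records the models, the
parameter choices, and the places where design was genuinely open.

## Mass arithmetic

All masses are monoisotopic; the MALDI readout of this workflow reports
monoisotopic $[M+H]^+$, and average masses are deliberately not offered.
A linear peptide is the residue-mass sum plus one water; a head-to-tail
cyclic backbone has no terminal water.  The cysteine states are:

* **oxidized** — each disulfide removes two hydrogen atoms
  ($2 \times 1.007825$ Da);
* **reduced** — free thiols (the reference state);
* **carbamidomethylated (CAM)** — iodoacetamide adds $+57.021464$ Da per
  reduced Cys, i.e. $+58.029289$ Da per Cys relative to the native
  disulfide form.

Charging uses the proton mass ($1.007276$ Da), reduction the hydrogen-atom
mass ($1.007825$ Da); the half-millidalton difference is far below every
tolerance in play but kept physically correct.  Non-canonical residue
letters (B, Z, X, U, O) are rejected rather than approximated, with the
offending position named.

For the two isolated *Allexis cauliflora* peptides bundled with the
package this arithmetic reproduces the reported signals:

```{r}
sapply(alca_peptides(), function(p) round(mz(peptide_neutral_mass(p)), 1))
```

## Derivatization-series screening

The screen looks for quadruples of peaks across four spectra of the same
extract: native, DTT-reduced ($+n \times 1.0078$ Da for $n$ cysteines),
IAA-alkylated ($+n \times 57.0215$ Da further), and GluC-processed
($+18.0106$ Da further if the backbone was cyclic with a single Glu).  For
every native peak and every candidate cysteine count $n \in \{1..10\}$
(both parities, since other cystine-rich families are possible) the chain
is followed; among candidates with equally many matched steps, the $n$
with the smallest total absolute deviation wins.

Two tolerance modes exist because two use cases exist.  Instrument-grade
peak lists are matched at **±25 ppm** per step (the default).  Published
tables rounded to one decimal need an **absolute mode** (0.2 Da): rounding
alone contributes up to 0.05 Da per value, and the bundled 18-row
*A. cauliflora* table has step deviations up to 0.17 Da (~47 ppm), so at
strict 25 ppm only 10 of its 18 rows survive all three steps (six more
lose only the ring-opening step and two drop entirely), while at 0.2 Da
all 18 classify as six-cysteine cyclic — the published conclusion.

Chaining is anchored **on the previously matched peak** by default
(`from_previous_observed`): each step's deviation is then a single
measurement error rather than an accumulated one, which is also how the
deviations in published tables behave.  Anchoring everything on the native
peak (`from_native`) is available.

Series claim their companion peaks injectively.  Claims are ranked by
number of matched steps first, then mean per-step deviation, then native
m/z.  Ranking by raw deviation totals would be wrong: a two-step
(incomplete) chain always has a smaller sum than a three-step one, so
spurious partial chains would steal peaks from genuine complete series.

A structural limitation worth recording: two analytes whose native masses
differ by $k \times 58.029$ Da (with a third signal near
$k \times 1.008$) produce derivatization ladders that alias onto each
other under a cysteine count off by $k$.  No shift arithmetic can separate
them; the deviation-minimizing rule picks whichever chain is numerically
closer.  Real screened extracts are sparse enough that this rarely arises
(the published table's signals sit ≥10 Da apart, off that lattice), and
the synthetic generator plants extracts the same way (see below).

The optional idea of flagging extra linearized-list peaks as internal GluC
fragments is not implemented: without sequence knowledge the screening
stage cannot compute internal fragment masses, and flagging arbitrary
extra peaks would be noise.

## In-silico proteolysis of cyclic backbones

Cleavage rules are site-specific: GluC after Glu; trypsin after Lys/Arg
unless Pro follows; chymotrypsin after Phe/Tyr/Trp/Leu/Met, never after
Ile — the beta-branched side chain hinders the enzyme, which is exactly
what makes chymotryptic evidence informative for Ile/Leu calls.  A strict
F/Y/W chymotrypsin mode is available.  The Pro block for trypsin follows
the standard rule; no K-P/R-P motif occurs in the alca peptides, so their
digests are insensitive to that choice.

For a cyclic parent with $k$ sites the complete digest yields exactly $k$
fragments (arcs between consecutive sites, wrapping modulo the length);
partial products with up to `max_missed` uncut internal sites are added,
and the $k$ full-length single-cut linear forms are always emitted and
flagged, because they are the MS/MS precursors of interest even when they
exceed the missed-cleavage allowance.  `max_missed` defaults to 2 — the
full-length tryptic partial of alca 1 spans two internal sites.  Every
fragment is a linear peptide (one water gained per cut); a digest
conserves mass: the $k$ complete fragments sum to the cyclic parent mass
plus $k$ waters, which is tested, as is invariance of the fragment
multiset under rotation of the written sequence.  Coordinates are 1-based
in the sequence as written, which by the field's convention starts
immediately after the native ligation site.

Digests of an oxidized parent report masses for free-thiol fragments:
disulfide connectivity cannot be carried into fragments from sequence
alone, and the workflow digests CAM material anyway.

## MS/MS annotation

Only singly charged b and y ions with optional $-17$ (NH$_3$) / $-18$
(H$_2$O) losses are modelled — the MALDI post-source-decay context; a/x/c/z
series are excluded.  The matching tolerance defaults to 0.3 Da, a typical
MALDI-TOF/TOF fragment accuracy, and is exposed.  Matching is greedy by
smallest absolute error, and one peak may support at most one ion per
(series, index), so loss variants cannot double-count a peak.

Residue $j$ counts as supported when a matched ion places a verified bond
boundary adjacent to it; full coverage means at least one y- or b-series
signal for every residue — either series suffices.  Annotations of
differently opened linear forms of one cyclic parent are combined by
mapping each back to cyclic coordinates and OR-ing the support; this is
how a cyclic peptide reaches full coverage when each single digest leaves
gaps.

Ile/Leu resolution uses chymotryptic fragments: a `J` position is called
Leu when an observed fragment boundary requires cleavage right after it,
and Ile when fragments span it uncut and it is never a boundary.  Because
an observed mass can be consistent with several arcs (every single-cut
full-length form shares one mass), evidence is taken only where all
consistent arcs agree — a boundary call needs a unanimous end, a
spanned-uncut call needs coverage under every interpretation.  Calls are
evidence-tagged and deliberately not absolute: incomplete digestion can
mask a Leu, and homology-based assignments can be supplied by the caller
under their own tag.

## Inhibition assays

Percent remaining activity is $I = 100 \, v_i / v_o$ on
background-corrected initial velocities.  Michaelis–Menten and
four-parameter logistic (4PL) fits use Levenberg–Marquardt least squares
(`minpack.lm`), on replicate means by default (the common plate-fit
convention; per-replicate fitting is a flag).  The 4PL is

$$Y = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}
      {1 + 10^{(\log_{10}\mathrm{IC}_{50} - X)\,\cdot\,\mathrm{Hill}}}$$

with $X$ the log$_{10}$ concentration; with $Y$ as remaining activity an
inhibition curve has a negative Hill slope.  Start values are
$\mathrm{Top} = \max Y$, $\mathrm{Bottom} = \min Y$,
$\log\mathrm{IC}_{50} =$ the $X$ nearest the midpoint response, Hill
$= -1$, with Hill bounded to $[-10, 10]$ — a robust default for a fit
that GUI packages perform with unstated settings.  The fitted curve is
reported in the canonical orientation $\mathrm{Bottom} \le \mathrm{Top}$
(the model is invariant under swapping asymptotes and negating Hill).
Flat responses or dose ranges that never cross the transition leave the
midpoint unidentified; such fits are flagged non-converged rather than
returned silently.  Concentrations are whatever unit the data are in
(µM for purified peptides, µg/mL for extracts); IC$_{50}$ comes back in
that unit, and unit rescaling shifts only $\log\mathrm{IC}_{50}$.
Normalization to the enzyme control or to the maximum response is applied
to the data before fitting when requested — normalizing afterwards is
possible by rescaling the fitted asymptotes, but the pre-fit order is the
default because it matches how plate data are usually reduced.  No
automatic outlier rejection is done.

## Sequence analytics

The six intercysteine loops are numbered I–VI with loop 6 holding the
native ligation site.  Because the backbone is a circle the numbering
needs a rotation-invariant anchor: when the sequence carries exactly one
Glu — the conserved loop-1 glutamate that makes GluC opening single-cut —
Cys I is chosen so that loop 1 contains it; otherwise the first written
cysteine anchors.  Moebius vs. bracelet classification is the presence
vs. absence of Pro in loop 5.  From sequence alone only Pro presence is
observable, not cis/trans geometry, so the call is a sequence-level proxy
and says so in its output.

Homology scoring uses the field's minimal convention: identical characters
score 1, no gap penalties.  The optimum of that scheme is exactly the
longest common subsequence, computed by dynamic programming and verified
in the tests against an exponential-time recursive oracle and an
independent alignment engine.  Since no cell score can be negative under
this scheme, the local (Smith–Waterman) optimum coincides with the global
one; the `mode` flag is accepted for interface completeness and documented
as equivalent rather than pretending to be a second algorithm.  Queries
are scored as written (mature-domain convention); a best-over-rotations
mode exists for cyclic queries.  Frequency-logo input is reduced to the
per-column residue frequency matrix over non-gap characters (gap fraction
reported separately); rendering itself is left to logo tools.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable offline, with ground truth.

* `generate_cyclotide_like` builds cyclic six-Cys peptides with the
  canonical loop architecture, one Glu in loop 1, an Asn/Asp ligation
  residue ending the written sequence, and loop-length ranges giving
  27–33 residues.  Native masses are rejection-sampled into the
  2900–3550 Da window in which cyclotide signals are read out, pairwise
  separations are kept ≥ 6 Da (real screened extracts sit ≥ 10 Da apart),
  and spacings within 0.3 Da of $k \times 57.02$ / $k \times 58.03$
  (k ≤ 5) are rejected so that planted ladders cannot alias onto each
  other — without that, the recovery ground truth would be ill-defined in
  the same way co-eluting isobaric analytes are.
* `simulate_derivatization_peaklists` plants the exact chemical shifts and
  models measurement error on each observed **shift**: every derivative
  peak carries an independent Gaussian ppm-scale error (default 10 ppm)
  relative to the peak it chemically derives from, which is precisely the
  quantity the screen evaluates.  Decoy peaks are uniform over each list's
  window but kept 3 × tolerance away from true peaks, so false-positive
  counts are well-posed.  Dropout is per peak on the derivative lists.
* `simulate_msms` samples each base ion with probability 0.8 and each loss
  variant with 0.2, jitters m/z by 0.02 Da, and adds uniform noise peaks.
* `simulate_dose_response` draws 4PL responses with multiplicative
  Gaussian noise (default CV 5%, the plate-reader error mode) on a
  default design of 8 log-spaced doses over 0.1–60 with 5 replicates.

What the generators do **not** emulate: MALDI intensity and ionization
efficiency, isotope envelopes, profile-mode peak shapes, chromatographic
co-elution, and calibration drift that correlates errors across an entire
spectrum.  Passing tests therefore demonstrate the correctness of the
arithmetic, matching, assignment and fitting logic under realistic error
magnitudes — not robustness to every pathology of real spectra.

## Problem sizes and numerical choices

The simulation-based checks run at sizes chosen to make their Monte-Carlo
error small relative to the margins they assert: 500 dose-response
datasets for the median-IC$_{50}$ and interval-coverage properties, and
40 independent 50-peptide extracts (2000 peptides) for screening recovery
at 8 ppm noise / 25 ppm tolerance, where the per-peptide recovery
probability is $(1 - 2(1 - \Phi(25/8)))^3 \approx 0.995$ and the pooled
estimate has standard error well under the asserted 1% margin.  Ties in
peak matching break toward lower m/z; duplicate m/z values within
$10^{-6}$ are rejected at the peak-list boundary; all random generation is
reproducible from a single integer seed.

## Known limitations

* Cysteine-count aliasing between analytes on the $58 k$ Da lattice is
  undetectable by shift matching alone (discussed above).
* cis/trans proline geometry — the actual Moebius/bracelet criterion — is
  not inferable from sequence; the classifier is a proxy.
* Ile/Leu calls inherit the completeness of the chymotryptic digest.
* Charge states above 1 are out of scope throughout (MALDI context).
* The 4PL standard errors are asymptotic (from the least-squares
  covariance); interval coverage is verified by simulation at the default
  design, not guaranteed for pathological designs.
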