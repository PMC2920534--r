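---
title: "From biopanning peptides to candidate antigens: the statistical model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From biopanning peptides to candidate antigens: the statistical model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimoscan)
library(dplyr)
```

## The problem

Biopanning a random-peptide phage-display library on a cancer patient's
serum antibodies yields a panel of short peptides (5–16 aa) that the
patient's IgG or IgM antibodies bind. Peptides that mimic *sequential*
(linear) epitopes carry a few residues of the real antigen, so a protein
database search can in principle reveal the antigen. The obstacle is purely
statistical: the recognized motifs are only 4–6 residues long, so a search
tuned for such short queries returns on the order of a hundred proteins per
peptide, almost all chance matches — and the chance of matching grows with
protein length, which is why very large proteins (mucin 16 at 14,507 aa,
nesprin-1 at 8,749 aa) accumulate multiple matches in almost any panel.

mimoscan implements the analysis that separates signal from this background:

1. a transparent short-peptide matcher replacing a short-query BLAST run;
2. an empirical chance-match null estimated from the same peptides spelt
   backwards;
3. per-protein significance by an exact binomial tail, length-normalized;
4. a motif-redundancy collapse so that peptides matching through one shared
   motif count once;
5. a Fisher's exact contrast of the panel against all other panels.

## The matcher

Exact mode (the default) reports every maximal ungapped window of at least
`min_exact_window` residues (default 5) shared between peptide and protein
with at most `max_mismatches` substitutions (default 0). "Maximal" means the
window cannot be extended one residue in either direction without leaving a
sequence or exceeding the mismatch budget. Window 5 with no mismatches is
the default because the motifs antibodies recognize are "identical or nearly
identical" fragments of 4–6 residues; window 4 also recovers 4-mer motifs
(such as the PWSK family) but is substantially noisier — at window 4 a
random peptide already matches roughly 2 % of 450-aa proteins by chance —
so it is left as an explicit flag. Scored mode approximates short-query
protein-search conventions (PAM30, exact 2-mer seeds, ungapped
score-maximal extension, minimum score 35) for users who want graded
similarity; all statistics downstream are mode-agnostic.

Matches are counted once per (peptide, protein) pair regardless of how many
sites match: the statistics count matching peptides, not sites. Homologous
proteins are independent rows — a peptide matching a conserved
fucosyltransferase motif hits FUT3, FUT5 and FUT6 separately, which is the
behavior a practitioner expects from database search output.

Coordinates are 0-based half-open inside the C++ core and 1-based inclusive
(the BLAST tabular convention) in every tibble and file the user sees.

## The reversed-peptide null

The chance-match frequency is estimated by searching the *reversed* panel
peptides ("spelt backwards") with byte-identical matcher parameters.
Reversal preserves length and composition but destroys genuine epitope
signal, making it a decoy search in the proteomics sense. For each protein,
let `M` be the number of distinct reversed peptides matching it, `N` the
number of peptides and `L` the protein length; the per-protein
length-normalized frequency is

  f_i = M / (N · L / 1000)   (matches per peptide per 1000 aa),

and the estimate reports the mean and standard deviation of `f_i` over
qualifying proteins. Against a full reference proteome the original
analysis conditioned on overrepresented proteins ("four or more matches");
the published value f = 0.02 ± 0.01 per 1000 aa is reproduced in magnitude
by desk-scale runs here (seed 1 of the worked pipeline below gives
f ≈ 0.026). The "± 0.01" is interpreted as the standard deviation of the
per-protein frequencies, the only definition consistent with reporting a
single spread; nothing downstream depends on this choice.

Two desk-scale facts shape the defaults:

* **Threshold.** Against a 300-protein synthetic database the expected
  per-protein reversed-match count is ~0.03, so the `M >= 4` rule selects
  essentially nothing and `estimate_null()` errors by contract rather than
  silently returning 0. Pipeline runs therefore default to
  `min_matches_threshold = 1`. Conditioning on `M >= 1` inflates `f`
  (a protein observed with one match among 70 peptides implies a large
  `f_i`), which is *conservative*: an inflated null makes candidate
  significance harder to reach, never easier.
* **Calibration.** `min_matches_threshold = 0` gives the unconditioned
  estimator over all proteins (zero-match proteins included), which is
  unbiased. The test suite verifies that under uniform composition it
  recovers the closed-form chance rate
  `1 − (1 − 20⁻ʷ)^((l−w+1)(L−w+1))`, length-normalized, within Monte-Carlo
  error over 20 seeds.

Palindromic peptides (fixed points of reversal) are kept: excluding them
would bias `N`, and no exclusion rule is part of the method.

## Scoring a candidate

For a panel of `n` matchable peptides (peptides shorter than the matcher's
window are excluded from `n` and the exclusion logged) and a protein of
length `L` with `k` distinct matching peptides:

* **Chance probability.** `p0 = min(1, f · L / 1000)` — chance matching is
  taken as directly proportional to protein length.
* **Motif collapse.** Peptides are grouped transitively: two peptides share
  a group when their matched protein intervals overlap *and* their matched
  substrings share a common substring of ≥ 4 residues. `k_eff` is the
  number of groups. Five peptides that all match glycogen phosphorylase
  through a common PWSK motif are one piece of evidence (`k_eff = 1`,
  `MOTIF_COLLAPSED`), negating the apparent multiplicity; four different
  peptides matching plexin B3 at unrelated sites keep `k_eff = 4`.
* **Binomial tail.** `p_binomial = P(X ≥ k_eff)`, `X ~ Binomial(n, p0)`,
  by direct summation of exact terms. The headline worked example: with
  f = 0.02 and L = 403 (a 403-aa demethylase), `p0 = 0.00806` and 2 of 3
  matching peptides give `p = 1.94e-4 < 0.001` — strong evidence the two
  peptides mimic real sequential epitopes. By contrast, at L = 14,507 aa
  `p0 = 0.29`, the expected chance matches among 70 peptides are 20.3, and
  7 observed matches give `p ≈ 1`: the `LENGTH_SUSPECT` flag (set when
  `n · p0 ≥ k`) marks exactly this situation.
* **Fisher contrast.** A one-sided exact hypergeometric tail on
  `(k_eff, n − k_eff)` vs `(k_other, n_other − k_other)`, where the other
  group pools all other panels (including the healthy-control panel by
  default; `exclude_panels` changes that). One-sided "greater" is the
  alternative that matches the scientific question (enrichment in this
  patient); a two-sided option is exposed. The published p-values for the
  two reconstructable contrasts (0.0009 and 0.006) cannot be reproduced
  from any 2×2 table recoverable from the published peptide counts — the
  enumeration-validated implementation gives 1.24e-3 for (2 of 3 vs 0 of
  67) and 1.16e-2 for (4 of 24 vs 0 of 46) — so the implementation is
  treated as authoritative and the discrepancy recorded here. Using
  `k_eff` rather than `k` on the panel side applies the motif-collapse
  argument consistently to both statistics, the stricter reading.
* **Multiplicity.** Benjamini–Hochberg q-values are computed per panel over
  proteins with `k ≥ 2` and reported, but not used for ranking — the
  original analysis performs no correction, and the q-values are offered as
  context only.

Candidates are sorted by `p_binomial`, then `p_fisher`, then `L`, then
protein id; ranking ties are therefore deterministic.

By default all counts are over unique peptide sequences, not phage copies:
clonal expansion of one insert is one antibody specificity amplified, not
independent evidence. `weight_by_copies = TRUE` switches both `n` and `k`
to phage counts for users who want the sensitivity analysis.

## The synthetic generator

`simulate_screen()` draws the study conditions every test runs under: a
protein database of i.i.d. sequences (uniform composition by default, so
the closed-form chance rate is exact; a natural-composition preset exists
for realism checks) with lognormal lengths (median 450 aa) plus fixed very
long decoys (14,507 and 8,749 aa) so length normalization is always
exercised; and panels with geometric clonal copy numbers (mean 2),
shared-motif families, epitope carriers and random background — the three
structural elements real panels show (clonal groups, motif-sharing groups,
singletons).

One design choice deserves its rationale. When a panel plants
`n_epitope_peptides` carriers, each carrier receives by default its **own**
epitope site of the planted protein (distinct, non-overlapping sites),
because that is what the positive case being emulated looks like: the two
peptides that identified the 403-aa antigen share no motif and mimic
different sequential epitopes, which is precisely why they count as two
independent matches. Planting one shared site would make the generator's
positive control indistinguishable — by the method's own collapse rule —
from the shared-motif artifact it must reject, and the planted antigen
would never reach significance at small `n`. The `shared_epitope = TRUE`
switch generates that collapsed variant deliberately; the test suite uses
it to verify the negative behavior. Epitope mutations are substitutions
only, matching the ungapped matcher.

What the generator does *not* emulate: selection-round dynamics, phage
amplification bias, antibody affinity, real proteome composition and
homology structure (paralog families, low-complexity and repeat regions).
Chance-match rates in real proteomes are somewhat higher than the i.i.d.
uniform closed form predicts, which is one reason the pipeline estimates
`f` empirically instead of using the closed form. Passing tests on
synthetic data therefore demonstrate correctness of the machinery and
calibration under the stated laws, not performance on any particular real
proteome.

## Problem sizes and numerical choices

The shipped tests and examples run at desk scale: proteomes of 50–300
proteins plus the two long decoys, panels totalling ~70 peptides (the scale
of the original screen), 8–20 seeded replicates per stochastic property.
These sizes were chosen so that every property that scales (oracle
equivalence, null calibration, planted-antigen recovery, false-positive
control) is exercised with margins that do not depend on the database being
large.

* Exact binomial and hypergeometric tails are direct sums of `dbinom` /
  `dhyper` terms; no approximations anywhere.
* Best-hit tie-breaks: higher score, then smaller protein start, then
  smaller peptide offset. Clone-summary ties break lexicographically.
* Reports print floats with 6 significant digits (scientific below 1e-4)
  and are byte-identical for identical inputs; the JSON report mirrors the
  TSV at full precision and is the exact round-trip medium.
* Sequences are restricted to the 20 standard amino acids at parse time;
  B/J/O/U/X/Z are rejected because every statistic assumes a fixed
  20-letter alphabet. An `allow_x` escape hatch maps X to a residue that
  never matches.
* Degenerate inputs fail loudly: empty proteomes, panels below the minimum
  null size (10 peptides), thresholds no protein reaches, and
  forward/null parameter mismatches are errors, not warnings.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- list(
  simulate = list(
    seed = 1, n_proteins = 300,
    panels = list(
      list(patient_id = "A", n_unique = 3, n_epitope_peptides = 2,
           planted_protein = 1),
      list(patient_id = "B", n_unique = 13), list(patient_id = "C", n_unique = 13),
      list(patient_id = "D", n_unique = 13), list(patient_id = "E", n_unique = 14),
      list(patient_id = "F", n_unique = 14))),
  match = list(min_exact_window = 5),
  null = list(min_matches_threshold = 1))
res <- run_pipeline(cfg, "run1")
dplyr::filter(res$candidates, panel_id == "A/IgG")
autoplot(res$candidates)
```

At seed 1 this recovers the planted 400-aa antigen at rank 1 with
`p_binomial = 3.3e-4` (n = 3, k_eff = 2, f ≈ 0.026), while the 14,507-aa
decoy drawing a single chance match sits at `p ≈ 0.76` with
`LENGTH_SUSPECT`.

## Known limitations

* Only sequential (linear) epitopes are in scope; conformational and
  carbohydrate mimics require orthogonal (proteomic) identification, and
  panels dominated by them will simply produce no significant candidate.
* The matcher is ungapped by design; an epitope interrupted by an insertion
  will be found only as its flanking fragments.
* The reversed-peptide null inherits the composition of the panel peptides;
  heavily biased panels (e.g. proline-rich) shift `f` accordingly, which is
  intended — but it means `f` from one screen should not be reused for
  another.
* With very few peptides the null is noisy (`estimate_null()` warns below
  30, refuses below 10); the Fisher contrast is then the more stable of the
  two statistics.
* The exact parameter set of the original short-query BLAST runs is not
  recoverable, so agreement with the historical per-peptide protein lists
  is not attempted; the matcher's contract is defined by its own
  brute-force oracle instead.
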