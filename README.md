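# mimoscan

Identify candidate tumor-associated antigens from random-peptide
phage-display biopanning on patient serum antibodies.

## The problem

Screening a random-peptide phage-display library on a cancer patient's
serum IgG/IgM antibodies yields a panel of short peptides (mimotopes) the
antibodies bind. When a peptide mimics a *sequential* epitope, it shares a
4–6 residue fragment with the real antigen, so a protein database search
can reveal the antigen — except that fragments this short match hundreds of
proteins by chance, and the chance grows with protein length, so huge
proteins (a 14,507-aa mucin, an 8,749-aa nesprin) pile up spurious matches
in almost any panel. mimoscan implements the statistical analysis that
separates real antigens from this background.

## The model

For a panel of *n* unique peptides and a protein of length *L* (aa):

* **Chance-match frequency** *f* (matches per peptide per 1000 aa) is
  estimated empirically by searching the same peptides in reverse
  orientation ("spelt backwards" decoys) with identical matcher
  parameters: per protein, `f_i = M / (N · L / 1000)` with *M* the distinct
  reversed-peptide matches and *N* the peptide total; *f* is the mean of
  `f_i` over qualifying proteins (± their SD).
* **Chance probability** per peptide: `p0 = min(1, f · L / 1000)`.
* **Motif collapse**: peptides whose matches overlap on the protein and
  share a ≥ 4-residue substring count as one independent match; `k_eff` is
  the number of independent match groups among the *k* matching peptides.
* **Binomial tail**: `p_binomial = P(X ≥ k_eff)` for
  `X ~ Binomial(n, p0)`, by exact summation.
* **Fisher contrast**: one-sided exact hypergeometric tail of
  `(k_eff of n)` in this panel vs `(k_other of n_other)` pooled over all
  other panels.
* Proteins whose expected chance matches `n · p0` reach the observed *k*
  are flagged `LENGTH_SUSPECT`; optional expression data flag candidates
  overexpressed uniquely in the matching patient's tumor
  (`EXPRESSION_SUPPORTED`).

The short-peptide matcher itself is transparent: exact mode reports every
maximal ungapped window ≥ 5 aa (configurable to 4, with an optional
mismatch budget); scored mode offers PAM30-seeded ungapped extension.
A seeded synthetic generator (proteome + panels with planted ground truth)
makes the whole pipeline testable without downloads, and BLAST
outfmt-6-style tables can be imported in place of the built-in matcher.

## Worked example

```r
library(mimoscan)

# The headline calculation: 2 of patient A's 3 IgG peptides match a 403-aa
# protein; is that chance, given f = 0.02 per 1000 aa?
p0 <- chance_prob(0.02, 403)        # 0.00806
binomial_tail(3, 2, p0)             # 0.000193844  -> well below 0.001
fisher_contrast(2, 3, 0, 67)        # 0.00124: no other panel matches it

# The length trap: a 14,507-aa protein with 7 matches among 70 peptides
binomial_tail(70, 7, chance_prob(0.02, 14507))   # 0.99997 -> chance alone

# Reference panels with clonal copy numbers
clone_summary(table1_panels())
#   A/IgG: n_unique 3, n_phage 18, top insert TGVRGQRISQ in 9 of them
scan_pattern(table1_panels(), "KxxGHH")
#   B/IgG: 4 distinct inserts carry the motif, on 5 phage particles

# End-to-end on synthetic data with a planted antigen
cfg <- list(
  simulate = list(seed = 1, n_proteins = 300,
    panels = list(
      list(patient_id = "A", n_unique = 3, n_epitope_peptides = 2,
           planted_protein = 1),
      list(patient_id = "B", n_unique = 13), list(patient_id = "C", n_unique = 13),
      list(patient_id = "D", n_unique = 13), list(patient_id = "E", n_unique = 14),
      list(patient_id = "F", n_unique = 14))),
  null = list(min_matches_threshold = 1))
res <- run_pipeline(cfg, "run1")
dplyr::filter(res$candidates, panel_id == "A/IgG")
#   rank 1: the planted 400-aa antigen, k_eff = 2 of n = 3,
#           p_binomial = 0.000325 (f estimated at 0.026 from 70 reversed
#           peptides); the 14,507-aa decoy ranks last, LENGTH_SUSPECT
autoplot(res$candidates)
```

A thin command-line wrapper ships at `inst/cli/mimoscan.R`
(`simulate`, `search`, `motifs`, `scan`, `null`, `run-all` subcommands);
the methods vignette (`vignettes/antigen-ranking.Rmd`) documents the model,
its assumptions, parameter choices and limitations.

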