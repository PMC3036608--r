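---
title: "Methods: degenerate-motif screening, comparative-CT quantification and transfer statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degenerate-motif screening, comparative-CT quantification and transfer statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes, the
assumptions behind each stage, and the design choices made where the
problem left the design open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Promoter model and coordinates

A *promoter record* is a fixed-length window of genomic sequence
immediately 5' of an anchor, stored 5'→3' on the gene's coding strand with
its last base adjacent to the anchor. The default anchor is the **start
codon**, because motif positions in this literature are reported as
"bp upstream of the start codon"; transcription-start anchoring is
available (`anchor = "transcription_start"`) since pre-extracted upstream
datasets do not always state their convention, and the two differ by the
5' UTR length. The position convention is fixed by the distance of a
site's 5'-most base: a window starting at 1-based offset $i$ of an $L$-bp
promoter lies $u = L - i + 1$ bp upstream, so a site fully inside a 500-bp
window has $8 \le u \le 500$ for an 8-bp motif.

Splice variants are independent records (ids like `AT1G22150.1`,
`AT1G22150.2`), not collapsed to loci — that is how upstream datasets
count "gene models" — with an optional locus-collapsed count
(`collapse_loci = TRUE`, strips the `.n` suffix).

Extraction from genome FASTA + GFF3 places a plus-strand window at
$[p - w,\, p - 1]$ for anchor position $p$ and window $w$, and a
minus-strand window as the reverse complement of $[p + 1,\, p + w]$;
multi-part CDS features anchor at the first coding base. Windows clipped
by a chromosome end are kept and flagged `truncated` rather than dropped:
a shortened promoter is still scannable, and the flag keeps the decision
reversible downstream.

Sequence alphabet: after uppercasing, `A,C,G,T,N` are kept and any other
valid IUPAC ambiguity letter in *input sequences* becomes `N`. Soft-masked
(lowercase) input is uppercased and scanned — no masking rule is imposed.

## 2. Degenerate motif scanning

An IUPAC pattern is compiled to per-position base subsets (the P1BS
element `GNATATNC` → `{G},{ACGT},{A},{T},{A},{T},{ACGT},{C}`). A window
matches a strand iff, read 5'→3' on that strand, every base is in its
position set. Three deliberate rules:

* **`N` in the sequence never matches**, including against pattern `N`:
  an unknown base is evidence of nothing. A consequence worth knowing:
  promoters containing `N` can only lose hits.
* **Both strands are scanned by default**, with minus-strand matching
  implemented as forward matching of the reverse-complemented pattern.
  For a self-reverse-complementary pattern (P1BS is an imperfect
  palindrome: its reverse complement is again `GNATATNC`) the two strands
  select identical windows, so each is reported exactly once with strand
  `±`. Forward-only and both-strand screens are therefore provably
  identical for P1BS — the original screen's unstated strand policy
  cannot change a presence/absence count.
* **Overlapping matches are all reported.** The per-gene screen statistic
  is presence/absence, so overlap policy cannot change the gene count
  either.

The scanner uses per-position 256-slot byte lookup tables over the raw
character codes — linear time, no compiled code needed at these scales
(a 33k × 500 bp screen takes seconds). Its correctness is not argued but
tested: a naive per-window set-membership oracle must agree *exactly* on
random sequences and random IUPAC patterns (test suite, criterion 2).

Under i.i.d. uniform bases the per-window match probability for
`GNATATNC` is $4^{-6} \approx 2.441\times10^{-4}$ (six constrained
positions), and the naive independence approximation for a 500-bp
promoter gives $1 - (1 - 4^{-6})^{493} \approx 0.113$ for the chance of
at least one hit. Windows overlap, so the suite computes the *exact*
probability by dynamic programming over the last seven bases (a 16,384
state chain) and checks a 10,000-promoter simulation against the exact
binomial 99% interval around it.

## 3. Comparative-CT quantification

Per biological replicate,
$\Delta CT = \overline{CT}_{\text{target}} - \overline{CT}_{\text{ref}}$
(technical replicates averaged on the CT scale),
$\Delta\Delta CT = \Delta CT - \overline{\Delta CT}_{\text{calibrator}}$,
and $\log_2 RQ = -\Delta\Delta CT$. Choices and why:

* **Efficiency is assumed exactly 2** in quantification. The dilution
  series screen ($E = 10^{-1/\text{slope}}$, pass at $E \ge 1.85$,
  ideal 2.0) is quality control for primer pairs, not a Pfaffl-style
  correction — that is what "comparative CT method" means, and mixing the
  two would silently change every reported value.
* **Calibration is per tissue**: the calibrator ΔCT is the mean over the
  calibrator condition's biological replicates *of the same tissue*,
  because root and shoot series are plotted as separate series against
  the same control condition. A direct consequence is the identity that
  the calibrator condition's summary is 0 by construction.
* **Technical outliers are flagged, never dropped** (range > 0.5 cycles
  → attribute `wide_technical_range`): silent dropping is the classic
  irreproducibility source in qPCR pipelines.
* **SD is reported across biological replicates on the log₂ scale**
  (`n_bio ≥ 2` required for an SD). Error bars of log₂ values — not log₂
  of error-barred quantities — is the interpretation implemented and
  documented, matching how log₂ expression panels are drawn.

Shift invariance (adding a constant to every CT of one replicate changes
nothing — it models a loading artifact absorbed by the reference gene) and
exponentiation consistency ($RQ = 2^{\log_2 RQ} = 2^{-\Delta\Delta CT}$
exactly) are tested as properties.

## 4. Transfer percentages and group statistics

`transfer_percent` is the destination-organ fraction of whole-plant label
×100; the two directions are complementary on one plant's counts (sum to
100, a tested invariant). Zero total counts is an error, not a 0.

`compare_groups` is one-way ANOVA + Tukey HSD with the vs-reference
subset reported (mutants are starred against wild type) and the full
pairwise matrix attached. Two non-obvious choices:

* **Degenerate zero-variance data** (every group constant) would make the
  F statistic 0/0; significance is then decided by exact equality of
  means. This keeps the extreme-separation case
  (`{0,0,0}` vs `{100,100,100}`) significant without special-casing
  downstream code.
* **Calibration of the starred subset.** Tukey's HSD controls the
  family-wise error over *all* pairwise comparisons at α. Restricting
  attention to the 3 of 6 comparisons that involve the reference is
  necessarily conservative: an independent `ptukey`-based simulation
  (50,000 null replications, 4 groups, n = 4) puts the vs-reference null
  rate at 0.0298 against a full-family rate of 0.0501. The acceptance
  suite checks both, each against its own simulated value — asserting
  0.05 for the subset would be asserting a miscalibrated procedure.

Replicate units: for anion concentrations one pool of ≥ 10 plants is one
replicate (biological repeats n ≥ 3); for tracer measurements the plant
is the unit, and because published transfer tables give mean ± SD without
n, the replicate count is an explicit argument (`table1_tracer_specs(n)`,
default 4) — never guessed silently.

## 5. What the generators emulate — and what they do not

* `synth_promoters`: i.i.d. background from a chosen base composition
  (uniform, or an Arabidopsis-like 36% GC preset — chance P1BS frequency
  depends on composition, so it is explicit) with motif instances written
  at exact distances/strands, degenerate positions instantiated randomly
  or as given. It emulates *positional truth*, not genomic realism: no
  repeats, no dinucleotide structure, no chromatin context. A green
  recall test establishes coordinate bookkeeping, not biological
  discovery power. A `{C,G}`-only background makes chance matches
  impossible and is used for the zero-false-positive checks.
* `synth_qpcr`: reference CT = baseline + replicate drift + biological
  noise; target CT shares the replicate drift (so normalization removes
  it exactly), offset by `gene_offset` − true log₂ effect; technical
  noise on every well. Defaults: baseline 20 cycles, offset 5, biological
  SD 0.2, drift SD 0.2, technical SD 0.15, n_bio 3, technical
  triplicates — the design grid is the two-genotype × two-tissue ×
  four-treatment starvation layout. No amplification-curve or melt-curve
  simulation: CT values are the model's primitives.
* `synth_groups`: normal draws per group from mean ± SD specs, truncated
  at 0 for physical quantities (a modelling choice, documented, not a
  data claim; with the tracer parameters it matters only for the
  smallest-mean group at ~1% of draws). The `ptukey` power oracle on the
  published tracer parameters gives flag rates of 0.666 (phr1), 0.879
  (sultr1;3) and 0.045 (sultr2;1) vs WT and 0.612 for the joint starred
  pattern — so the published star pattern is the *majority* outcome, not
  a certainty, and the acceptance test checks rates within binomial 99%
  bounds rather than asserting the pattern for every seed.

All generators require an explicit integer seed and are byte-reproducible
under it.

## 6. Numerical and degenerate-input decisions

* Promoters shorter than the pattern scan to an empty hit list, not an
  error; an empty promoter set screens to zero counts.
* Records longer than the declared window are a hard error naming the
  ids (silent clipping would corrupt upstream-distance coordinates).
* OLS slope for efficiency QC needs ≥ 3 distinct dilutions; a
  non-negative slope fails with a diagnostic instead of producing a
  nonsensical efficiency.
* Ties and ordering: screen output follows input order; hits within a
  promoter are ordered by offset. JSON/TSV outputs are byte-identical
  across reruns at a fixed seed (tested).
* Seeds are plain R `set.seed` integers; sub-stages of the pipeline
  driver derive fixed offsets (seed+1, +2, +3) so stages are individually
  reproducible.

## 7. Known limitations

* No position-weight-matrix scoring or binding-affinity model — the
  screen is exact-set matching, as degenerate-consensus screens are.
* No motif enrichment statistics against gene-set backgrounds.
* The genome-wide reproduction of the pinned upstream dataset's counts
  (33,282 models scanned) requires that external file; the package scales
  to it, but the desk-scale suite verifies the convention-fixing examples
  (432 / 297 bp positions, `GGATATTC` / `GGATATAC` words) on constructed
  fixtures.
* `extract_upstream` assumes a well-formed GFF3 with CDS `Parent` (or
  mRNA `ID`) attributes; trans-spliced genes and transcript assembly are
  out of scope.
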