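---
title: "Methods: signal-sequence detection at structural-variant breakpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal-sequence detection at structural-variant breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssScreen)
```

## The screen and what the package computes

A forward genetic screen reads out mutations of a single selectable locus:
cells that inactivate *HPRT1* survive thioguanine (positive selection) and
die in HAT medium (negative selection), so the X-linked, functionally
hemizygous gene acts as a mutation reporter. Amplicon sequencing of the
~43 kb gene body in selected and unselected populations, in a transposase-
expressing cohort and a control cohort, yields small-variant calls and
structural-variant (SV) breakpoint calls. The question the analysis answers
is whether SV breakpoints in the transposase cohort carry a specific signal
sequence — an inverted-terminal-repeat-like motif — that the control cohort
lacks, and whether the cohorts differ in rearrangement burden.

`pssScreen` implements that analysis as a tested pipeline:

1. **Detection** (criteria i–iii). For each SV, the two breakpoint flanks
   are extracted in *inward* orientation (read from the breakpoint into the
   rearranged segment; the right flank is reverse-complemented). In this
   frame an inverted terminal repeat is a plain forward match between the
   flanks. Criterion i demands at least 50 % identity starting less than
   4 bp from the breakpoint; criterion ii rejects aligned segments with
   single or tandem repeats longer than 5 bp; criterion iii removes
   candidates that match passing alignments in the control cohort.
2. **Motif summary.** Candidates are reported 5′→3′ with the breakpoint at
   the 3′ terminus, so they are already registered: stacking right-justified
   gives a breakpoint-anchored alignment, a position frequency matrix, and
   per-column information content `IC_j = 2 + Σ_b p_b log2 p_b` (bits).
3. **Screen statistics.** Mutational frequency
   `−ln(X_S/N_S) / −ln(X_0/N_0)`, clonogenic efficiency `X/N`, the exact
   Poisson rate-ratio test, the exact two-sided binomial test, and 40-bp
   windowed variant profiles with exonic/intronic comparisons.
4. **Synthetic data.** A generator that emulates the screen's structure and
   carries a truth table, so recovery and specificity are measurable.

## Detection choices where the procedure was open

The published criteria leave several details unstated; the package fixes
them as follows and exposes each as a configuration switch.

* **Alignment model.** Ungapped, exhaustive over start offsets 0–3 on both
  flanks and aligned lengths ≥ 10 within a 20-bp window. Flanks are short
  and the criterion is a percent identity, not an alignment score, so gaps
  would add parameters without information. Ties are broken toward longer
  alignments, then smaller offset sums, then the smaller left offset; the
  test suite proves the search equal to brute-force enumeration.
* **Identity denominator.** Identity is `matches / aligned_length`
  (`identity_denominator = "aligned"`); the full-window reading
  (`"window"`) is available because the published phrasing does not decide
  it. `N` bases never count as matches.
* **Repeat rule.** "No single or tandem repeats longer than 5 bp" is read
  as: no homopolymer run > 5, and no periodic tract (period 2–5, at least
  two full unit copies, partial trailing copy included) of total length
  > 5. So `AAAAAA` and `ACACAC` fail, `AAAAA` and `ACACA` pass. The rule is
  orientation-invariant and applies to both aligned segments.
* **Control subtraction.** The published criterion only states that no
  passing alignments existed in the control set. Operationally, a candidate
  is removed when its sequence matches the aligned segment of any *passing*
  control pair at ≥ 0.80 identity (best over shifts ≤ 3). The stricter
  cohort-level reading — any passing control pair voids the run — is
  `control_mode = "cohort"`.
* **Flank side.** Flanks read *into* the rearranged segment
  (`flank_mode = "inner"`), consistent with a signal sequence at both
  termini of a rearranged element; `"outer"` reads away from it. Candidates
  are reported per breakpoint side; the per-SV and per-side tallies are
  both available because the published unit of counting is ambiguous.

## The exact statistics

The rate-ratio test conditions on the total count: under equal rates,
`c1 | c1 + c2 = n` is binomial with success probability `t1/(t1+t2)`. The
two-sided p-value is the sum of binomial point probabilities not exceeding
the observed one (the *minlike* convention, matching the behaviour of exact
reference-distribution implementations; the central doubling convention is
an option). The confidence interval is Clopper–Pearson on the conditional
proportion, mapped to the rate-ratio scale by `(π/(1−π))·(t2/t1)`; at
`c1 = 0` it is `[0, U]`, at `c2 = 0` `[L, ∞)`. The suite verifies the test
against full enumeration for all `c1 + c2 ≤ 40` (max |Δp| < 1e−12) and
against `stats::poisson.test`, and checks exact-test conservatism by
simulation (2,000 null replicates at mean 20: rejection ≤ 5 % + 2·SE).

The mutational frequency formula is strictly *decreasing* in the selected
colony count `X_S`: fewer surviving colonies make `−ln(X_S/N_S)` larger.
The worked case `X_S = 10, N_S = 10^5, X_0 = 2700, N_0 = 10^5` gives
`ln(10^−4)/ln(0.027) ≈ 2.550`.

## What the generator emulates — and what it does not

Defaults state the emulated world: a 43,000-bp locus at GC 0.41 with nine
exons of 60–300 bp (≥ 500 bp apart; exon length realism is out of scope),
two SV cohorts drawn from DEL/INV/DUP/TRA (weights 0.4/0.35/0.15/0.1),
rearranged segments of 500–10,000 bp, 13-bp elements that end in `GGG` at
the breakpoint-proximal terminus and contain no thymines in reporting
orientation, per-copy substitution noise, a 5-kb translocation partner
contig, and per-40-bp-window variant counts (0.2 events/window, 1,000
reads/window, 5× exonic boost under selection — chosen so the exonic excess
is unambiguous at amplicon-scale read counts, as in the screen it mimics).

Three generator decisions deserve emphasis:

* **Overwrite, not insert.** Elements are written over reference bases so
  SV coordinates stay valid; the assay observes rearranged genomes, and
  coordinate bookkeeping stays trivial.
* **Breakpoint windows, not whole segments, are disjoint.** Each SV models
  an independent cell; only the flank windows feed the analysis. Making
  whole 500–10,000 bp segments disjoint is geometrically impossible for the
  50–200 SV cohorts the validation demands in a 43-kb locus, so the
  generator instead keeps every breakpoint's ±20 bp window disjoint from
  all others and from exons. A planted element therefore never corrupts
  another SV's flanks, and planting never alters exonic sequence (keeping
  inactivation classification independent of planting).
* **Planted means detectable.** A planted element must *be* a valid signal
  sequence in its realized context. The flank bases beyond the element can
  extend the best alignment by chance and create a disqualifying repeat
  (e.g. an element ending `…TTCT` followed by a genomic `T` yields
  `CTTCTT`), in which case the truth table would claim a signal sequence
  the criteria correctly reject. The generator therefore verifies, before
  noise is applied, that the noise-free flanks pass criteria i and ii under
  the default detection configuration, redrawing the element otherwise.
  This is a well-definedness condition on the truth labels, not a tuning of
  detection thresholds.

A green recovery test therefore establishes that the detector finds
planted, criteria-valid elements and rejects motif-free breakpoints at the
configured identity; it does *not* establish performance on real
breakpoint-calling artefacts (soft-clip ambiguity, micro-homology,
coverage-dependent call quality), read-level error models, or genome-wide
backgrounds, none of which the generator simulates.

## Numerical and degenerate-input conventions

* Two-sided exact p-values use the customary `(1 + 1e-7)` relative
  tolerance when comparing point probabilities, capped at 1.
* A breakpoint closer than one flank window to a contig end (or a TRA
  without its partner contig) is skipped with a machine-readable reason,
  never a crash; skips and control-removals are logged in the candidate
  table's attributes and in `skipped.tsv`.
* Information content of a column with no contributing sequences is `NA`;
  `0 · log 0 = 0` elsewhere.
* An inversion whose breakpoints both lie outside the gene body inverts the
  gene intact and is classified non-inactivating; inactivation requires
  exon overlap (DEL/DUP), an in-gene-body breakpoint plus exon overlap
  (INV), or an exonic anchor (TRA).
* All generators consume seeds through fixed offsets of the configured
  seed, so every stage is independently deterministic; pipeline outputs are
  byte-identical across reruns of the same configuration.
* The run-config format is a minimal `section.key: value` text dialect
  (YAML is deliberately not a dependency).

## Known limitations

* Criterion iii is a sequence-similarity filter against control alignments;
  with small control cohorts a chance passing control pair can remove a
  true candidate (observed at roughly the per-mille level in simulation).
* The detector is ungapped by design; elements with indel-divergent termini
  would be scored only through their longest ungapped block.
* The windowed comparison aggregates reads within regions and treats reads
  as exposures; overdispersion between windows is not modelled, matching
  the exact-test framing rather than a count-regression one.
* Translocation partners are simulated as a single accessory contig; the
  pipeline uses only local anchor flanks, not genome-wide context.
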