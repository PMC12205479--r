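---
title: "Dissecting a nitrate-responsive regulatory circuit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a nitrate-responsive regulatory circuit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrocircuit)
```

# The problem

Plant roots adjust growth and nitrogen metabolism to nitrate availability
through a transcriptional cascade that converges on the NIN-like proteins
NLP6 and NLP7 and their direct target, the nitrite reductase gene *NIR1*.
Upstream of the NLPs sits a small transcription-factor sub-circuit —
ARF18, ARF9, DREB26 and (in Arabidopsis) ANAC032 — wired with
autoregulatory and feedforward loops. `nitrocircuit` implements the
dry-bench half of dissecting such a circuit:

1. extracting TSS-anchored regulatory regions and intersecting candidate
   binding sites with open chromatin;
2. scanning those regions for transcription-factor binding motifs with
   exact p-values;
3. assembling signed regulatory networks from layered evidence (yeast
   one-hybrid binding, in vitro binding, protoplast regulation assays) and
   censusing their motifs;
4. predicting the qualitative effect of single and higher-order knockouts
   on the circuit's transcriptional output;
5. comparing circuits across species through an ortholog map; and
6. the study-style quantification formulas (2^-ddCt, ratiometric
   dual-luciferase normalization, GO odds ratios).

A seeded synthetic-data module generates inputs with the statistical
structure each stage assumes, so the entire chain is testable without any
genome or sequencing download.

# Coordinate conventions

Intervals are 0-based and half-open internally, matching BED; GFF-like
annotation (1-based, inclusive) is converted on ingest. The promoter window
for a plus-strand gene with TSS `t` is `[t - up, t + down)`; for a
minus-strand gene it is `[t - down, t + up)` with
`tss_offset(pos) = t - pos`, so in both cases the interval's two ends map
to exactly `-up` and `+down` on the TSS-relative axis (negative upstream,
positive downstream). The half-open asymmetry mirrors onto the oriented
axis for minus-strand genes; hit coordinates from the scanner are always
reported on the oriented, TSS-relative axis. Region extents default to the
species presets `species_preset("At")` (2000/1000 bp) and
`species_preset("Sl")` (5000/2000 bp). Windows are clipped at chromosome
bounds and truncated where they overlap another protein-coding transcript,
keeping the TSS; truncation ignores non-coding features. Regions can be
extended per gene via explicit `upstream_len`/`downstream_len` arguments
when prior assay designs (e.g. yeast one-hybrid fragments) covered a longer
stretch; no default extension table is shipped because those coordinates
are assay-specific.

Peak merging unions overlapping *and* abutting (gap = 0) intervals and
keeps intervals separated by one or more bases apart — the conventional
semantics of interval-merge tools. Open-chromatin flags require at least
1 bp of overlap under the half-open convention.

# Motif scanning

Two motif representations are supported. A **PWM** carries per-position
base probabilities and a zero-order background; a pseudocount (default
0.01) is distributed proportionally to the background so log-odds scores
are finite. An **IUPAC pattern** is a degenerate consensus such as
`TGNCYYTT` (NLP6/7), `YCRCCGHC` (DREB26), `KACGTR` (ANAC032, via its close
relative ATAF1) or the auxin response elements `TGTCTC`/`TGTCGG`/`TGTCNN`;
these printed consensi are packaged in `nitrate_motifs()`.

## Exact p-values

`score_pvalue()` computes `P(score >= t)` for a random background k-mer by
dynamic programming over integer-discretized log-odds scores. Numerical
choices:

* initial granularity 1e-3, refined by factors of 8 until two successive
  refinements agree within `tol` (default 1e-8) or the state count would
  exceed `max_states` (default 4e6);
* an external threshold is compared with a motif-length lattice margin, so
  a word scoring *exactly* `t` always counts as `>= t` regardless of
  rounding direction — this makes the DP agree exactly with exhaustive
  enumeration on lattice-valued motifs (all the packaged consensi) and in
  the sparse score tail of smooth matrices, which is where scanning
  operates (p around 1e-4);
* in the bulk of a smooth matrix's score distribution the achievable
  accuracy is limited by the state cap (order 1e-5 for an 8-mer), which is
  irrelevant to site calling but worth knowing if the function is used as
  a general CDF.

During scanning, window scores and the null distribution share one integer
lattice, so window p-values are self-consistent by construction (the same
behaviour as FIMO); the minus strand is scored with the reverse-complement
matrix and assigned p-values from the forward null, exact for
strand-symmetric backgrounds such as the uniform default.

## Consensus matches and the p-value cutoff

A perfect match to a short degenerate consensus often carries a p-value
*above* the conventional 1e-4 window cutoff — e.g. `TGNCYYTT` matches 16
of the 65,536 8-mers, giving p = 2.44e-4 — so filtering consensus matches
by that cutoff would discard every one of them. The package therefore
applies `p_cutoff` to PWM log-odds windows only; exact degenerate matches
are always reported as candidate sites, carrying their background match
probability as `p_value`. This mirrors the source analysis, in which the
auxin-response hexamers were annotated as candidate sites regardless of
PWM score. Windows containing `N` are skipped in both modes: no defensible
score exists for them.

## Multiple testing and the ARF pair rule

q-values are Benjamini–Hochberg, with the family defined as **all windows
tested for one motif across the scanned region set** (both strands). Hits
at `q <= 0.05` are flagged high-confidence; consensus-rule hits are
retained either way, with the flag still reflecting their q-value. Pairs
of `TGTCNN` occurrences with an inter-motif gap strictly below 14 bp
(end-of-first to start-of-second) are annotated as composite ARF sites.
Only immediate neighbours in coordinate order pair, and any strand
combination pairs; the binding literature suggests orientation matters,
but since the rule as stated specifies no geometry, the permissive
strand-agnostic reading is the default and each pair records both strands
so stricter filters can be applied downstream.

# Circuit assembly and motif census

Networks are edge lists with a sign (`activating`/`repressing`/`unknown`),
a mode (`direct`/`indirect`), an evidence layer (`eY1H`, `in_vitro`,
`target_direct`, `target_indirect`, `transactivation`) and a species tag.
Layers answer different questions — binding is not regulation — so the
census runs on one layer at a time, and parallel edges from different
layers are kept distinct.

A feedforward loop is a direct edge `X -> Z` plus a distinct simple path
`X -> ... -> Z`; the classic triad has one intermediate, and longer paths
are reported separately as `multinode_ffl` (default census depth 2,
`max_path_len` to go deeper). Coherence compares the direct sign with the
product of path signs (`(-)(-) = +`); any unknown sign yields `unknown`.
In the packaged Arabidopsis direct network the census finds exactly one
triad — the repressor ANAC032 acting on *NIR1* both directly and through
the activator NLP7 — and classifies it coherent, while the tomato direct
network contains none at any depth. `enumerate_ffls()` is tested against
brute-force triple enumeration on random 12-node networks.

# Knockout prediction and downstream epistasis

Predictions run on the direct layer against the output node *NIR1*, which
stands in for the nitrate-responsive reporter (the reporter reads out the
NLP -> *NIR1* edge class). The net sign from a gene to the output is the
product of edge signs along each simple path; all-positive paths mean a
knockout lowers the output, all-negative means it raises it, conflicts are
`mixed`, no path is `unconnected`.

For higher-order knockouts the study's epistasis assumption — the
downstream factor's phenotype wins — is operationalized as reachability:
among knocked-out genes with a path to the output, gene `n` dominates
gene `m` iff `n` is reachable from `m` along direct edges. Genes with no
path to the output are excluded *before* dominance resolution; that is
what lets the nlp7 phenotype dominate a dreb26/nlp7 double in Arabidopsis,
where DREB26 itself is unconnected in the direct layer. Reachability
rather than distance-to-output is deliberate: it reproduces the stated
calls in which NLP7 is epistatic to ANAC032 even though both touch *NIR1*
directly, and DREB26 is epistatic to the ARFs in tomato. If several
maximal genes agree, their shared direction is returned; disagreements and
mixed signs are `indeterminate`.

One documented tension: the Arabidopsis ARF9 mutant is reported with a
lowered reporter response, but ARF9's only direct-layer edge (repression
of DREB26, from supplementary transactivation data) leaves it unconnected
to *NIR1*, because DREB26 has no outgoing direct edge in Arabidopsis. The
engine returns `unconnected` as the rule dictates; the comparison layer
marks such genotypes untestable rather than forcing a match.

Observed directions can be supplied directly or derived from luminescence
dose-response data: the mutant-minus-wild-type difference in mean
normalized luminescence is regressed on nitrate concentration, the
direction is the slope's sign, and a relative-change threshold (default
10% of the wild-type signal at the highest dose) guards against calling
noise.

# Cross-species comparison

Genes are first rewritten onto canonical ortholog groups (packaged map:
NLP6/NLP7 and the tomato NLP7A/B collapse to `NLP`; the two tomato
nitrite reductases collapse to `NIR`; ANAC032 has no tomato entry).
Duplicates collapse; conflicting signs within one canonical edge become
explicit conflict records rather than silently resolving. An edge is
**conserved** only if source group, target group *and sign* agree and the
edge is direct in both species — sign-level rewiring (tomato DREB26
repressing NLP7, where Arabidopsis has no such edge) is the study's
headline, so a same-topology, opposite-sign pair is classified `rewired`
and surfaced in both species-specific sets. Genes without an ortholog stay
in the species-specific output with an `ortholog_absent` flag.

# Quantification formulas

`fold_change_ddct()` implements
`ddCt = (Ct_target - Ct_ref)[TF] - (Ct_target - Ct_ref)[EV]`, returning
`2^-ddCt`; technical replicates average on the Ct scale. Ct values outside
10–40 warn but do not error (soft validation). `normalize_luminescence()`
divides reporter by constitutive control counts and then by the batch
calibrator ratio when supplied; calibration defaults to per-experiment
(pass per-plate ratios to calibrate per plate). `go_odds_ratio()` is the
printed ratio-of-frequencies with the `p < 0.05 & OR > 1` selection rule;
the enrichment p-value is an input column because the original values come
from a length-bias-corrected external tool, and the optional
`go_hypergeom_p()` fallback is a plain over-representation test, not an
equivalent.

# Synthetic data: what it emulates, and what it does not

* `gen_promoter()` — i.i.d. zero-order background with planted motif
  instances at known TSS-relative positions/strands and peaks covering a
  chosen fraction of planted sites. It emulates exactly the null model the
  p-values assume, which is what makes off-target counts testable against
  `2 * L * p_cutoff`; it does not emulate dinucleotide structure, repeats,
  GC heterogeneity or real chromatin, so passing tests say the scanner is
  correct and calibrated *under its own null*, not that real promoters are
  this clean.
* `gen_network()` — random signed digraphs containing exactly the planted
  feedforward triads (extra edges are rejection-sampled so no incidental
  loop appears; infeasible budgets error after bounded retries).
* `gen_parot()` — wild-type normalized luminescence follows a monotone
  dose response over 0/1/10 mM nitrate, default `(1, 3, 6)` — a reporter
  induction magnitude chosen once as realistic for protoplast
  dual-luciferase assays — with mutants scaled ×0.3 (lower) or ×2
  (higher), multiplicative lognormal noise of CV 0.2, and 4 biological
  replicates per condition. The scale factors are synthetic conventions,
  not measured effect sizes.
* `gen_qpcr()` — Ct tables built by inverting the ddCt formula, exact at
  zero noise, Gaussian on the Ct scale otherwise.

All generators are pure functions of their spec and seed and emit truth
tables, so parameter recovery is the acceptance surface for every
downstream stage.

# Problem sizes and determinism

The shipped tests and the acceptance script use 3 kb synthetic promoters
for recovery checks, a 100 kb background sequence for off-target
calibration, 200 random 12-node networks for the census oracle, 100
simulation seeds for reporter-direction recovery, and full enumeration of
all 4^k words (k ≤ 8) for the p-value oracle — sizes at which every oracle
is exact or near-exact while the whole suite runs in about a minute. All
randomness flows through explicit seeds.

# Limitations

* Signs are qualitative; there is no magnitude or dynamical (ODE/Boolean)
  modelling of the circuit, and post-translational NLP7 regulation
  (nitrate binding, phosphorylation, nuclear shuttling) is out of scope.
* Only zero-order backgrounds are supported for p-values, matching the
  original scan settings.
* The in vitro fixture reflects only interactions recoverable from the
  study's prose, which undercounts its own printed totals; the fixture
  header documents the discrepancy rather than resolving it.
* The packaged probability matrix is a synthetic stand-in for an
  empirical binding model and should not be used for real site calling.
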