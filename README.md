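# nitrocircuit

Dry-bench analysis of small nitrate-responsive transcription-factor
circuits, built around the ARF18/ARF9 – DREB26 – ANAC032 – NLP6/NLP7 –
NIR1 sub-circuit of *Arabidopsis thaliana* and its *Solanum lycopersicum*
counterpart. The package is for systems biologists who have layered
evidence about a small gene circuit — candidate binding sites, in vitro
binding, protoplast regulation assays, reporter readouts in mutants — and
want to turn it into signed network models, test those models' qualitative
predictions, and compare wiring across species.

## What it computes

**Cis-element calling.** TSS-anchored promoter regions (0-based half-open
coordinates; windows truncated at neighboring protein-coding transcripts),
open-chromatin peak handling, and FIMO-style motif scanning. PWM window
p-values are exact: for log-odds score *S* of a random k-mer under a
zero-order background, `score_pvalue()` computes P(*S* ≥ *t*) by dynamic
programming over integer-discretized scores, with Benjamini–Hochberg
q-values over all windows tested per motif (high confidence at q ≤ 0.05).
Degenerate consensi (TGNCYYTT, YCRCCGHC, KACGTR, TGTCTC, TGTCGG) are
matched exactly, and pairs of TGTCNN sites spaced < 14 bp apart become
composite auxin-response-factor sites.

**Circuit assembly and census.** Signed edge lists (activating/repressing,
direct/indirect, per evidence layer) build into networks; the census finds
autoregulation and feedforward loops — a direct edge X→Z plus a distinct
simple path X→…→Z — and classifies coherence by comparing the direct sign
with the product of path signs.

**Knockout prediction.** For a knockout set, path-sign propagation to the
output gene (*NIR1*, the proxy for the nitrate-responsive reporter) gives
the predicted reporter direction; in multi-gene knockouts the
downstream-most connected factor is epistatic (dominance = reachability
along direct edges). Predictions are scored against observed reporter
directions.

**Conservation.** Networks are rewritten onto canonical ortholog groups
(NLP6/7 and NLP7A/B → NLP, NIR1/NIR2 → NIR, …) and intersected; conserved
edges must agree in topology *and* sign, so sign-level rewiring is
surfaced explicitly.

**Assay quantification.** 2^−ΔΔCt relative expression with
ΔΔCt = (Ct_target − Ct_ref)[TF] − (Ct_target − Ct_ref)[EV]; ratiometric
dual-luciferase normalization with batch calibration; GO odds ratio
OR = (k_in/n_in)/(k_all/n_all) with the p < 0.05 & OR > 1 selection rule.

**Synthetic data.** Seeded generators for promoters with planted motifs,
peak tracks, signed networks with exactly k planted feedforward loops,
nitrate dose-response luminescence with genotype effects, and Ct tables
with known fold changes — so every stage runs and is testable offline.

## Worked example

```r
library(nitrocircuit)

## the packaged Arabidopsis direct regulatory network
net_at <- circuit_fixture("at_direct")
enumerate_ffls(direct_network(net_at))[, c("members", "coherence")]
#>                   members coherence
#> 1 AtANAC032/AtNLP7/AtNIR1  coherent
```

The one triad in the Arabidopsis direct layer is ANAC032 repressing
*NIR1* both directly and via the activator NLP7 — direct sign and path
sign are both repressing, hence coherent.

```r
## downstream epistasis: ANAC032 lies downstream of ARF18
predict_genotype(net_at, genotype(c("AtARF18", "AtANAC032")))
#> AtARF18/AtANAC032 -> higher (dominant: AtANAC032)
```

Both genes are connected to *NIR1*, ANAC032 is reachable from ARF18, so
the double knockout inherits the repressor knockout's raised-reporter
phenotype.

```r
## all ten tomato genotype predictions match the encoded observations
px <- parot_genotypes("Sl")
preds <- lapply(px$genotypes, predict_genotype, net = circuit_fixture("sl_direct"))
compare_to_observations(preds, px$observations)$summary
#>      match   mismatch untestable  unmatched
#>         10          0          0          0

## three direct regulatory edges are conserved across the two species
part <- intersect_networks(
  canonicalize(direct_network(net_at), ortholog_fixture(), species = "At"),
  canonicalize(direct_network(circuit_fixture("sl_direct")),
               ortholog_fixture(), species = "Sl"))
part$conserved
#>   source target       sign   mode n_merged
#> 1  ARF18 DREB26 repressing direct        1
#> 2   ARF9 DREB26 repressing direct        1
#> 3    NLP    NIR activating direct        2

## plant a consensus auxin response element and recover it by scanning
sp <- synth_spec(seed = 7, seq_length = 3000,
                 planted_motifs = data.frame(motif = "TGTCTC",
                                             position = -500, strand = "+"))
g <- gen_promoter(sp)
subset(scan_sequence(g$region, nitrate_motifs()$ARF_TGTCTC),
       start == -500)[, c("motif", "start", "end", "strand", "p_value")]
#>        motif start  end strand      p_value
#> 1 ARF_TGTCTC  -500 -494      + 0.0002441406
```

Coordinates are TSS-relative (negative upstream); the p-value is the
probability that a random hexamer matches the consensus under the uniform
background (1/4^6 ≈ 2.44e-4).

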