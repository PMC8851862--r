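---
title: "Screening genomes for unitary pseudogenes: models, thresholds, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes for unitary pseudogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A *unitary pseudogene* is a gene disabled outright: its single functional copy
carries ORF-disrupting mutations (premature stop codons, frame-breaking 1-2 nt
indels) and no paralog elsewhere in the genome covers for it. Genome-wide
screens for such losses are a workhorse of comparative genomics -- gene loss is
a major engine of lineage-specific adaptation -- but naive screens are
dominated by false positives: spliced-alignment artifacts, sequencing and
assembly errors, functional gene duplicates mistaken for the lost copy,
paralogs from large gene families, poorly supported reference gene models, and
compensatory frameshift pairs that restore the reading frame.

`pgloss` implements the full discovery cascade as reusable, tested components:

1. **map** -- locate candidate orthologous loci for each reference protein by a
   translated seed-and-extend search;
2. **align** -- frameshift- and intron-aware protein-to-genome dynamic
   programming over each candidate locus;
3. **call** -- convert alignments into annotated disruption records and
   classify each locus;
4. **filter** -- the ordered unitary-status and false-positive filter cascade,
   fully logged per gene;
5. **relax** -- a relaxed-selection gate on foreground/background dN/dS and a
   selection-intensity parameter *k*;
6. **stats** -- functional-group enrichment, convergent-loss overlap tests, FDR
   control, and conserved-set false-positive validation.

A synthetic-genome simulator with a machine-readable truth table supports
end-to-end benchmarking of the whole cascade; real genome screens use the same
code paths through FASTA/GFF3/OBO/GAF/newick inputs.

## Candidate loci: one search, two independent criteria

Classic screens require a locus to be found by *two* independent mappers
before trusting it. Without external binaries, `pgloss` preserves the
conjunctive logic with one seed-and-extend translated search that must satisfy
two separate criteria:

* **similarity**: the best ungapped segment's empirical E-value is at most
  `evalue` (default `1e-3`). E-values come from an extreme-value fit to the
  maximal scores of `n_decoys` (default 200) shuffled-protein searches against
  the same genome -- decoys and real proteins run through the identical
  two-hit-seeded path, so the calibration is internally consistent. This null
  is a pragmatic stand-in, not a replacement for analytic Karlin-Altschul
  statistics.
* **chain consistency**: hits must assemble into a colinear chain (protein and
  genome coordinates advancing together, gaps bounded by `max_intron`)
  covering at least `min_chain_cov` of the protein.

A locus failing either criterion is discarded. Overlapping loci (> 50% of the
shorter) merge before alignment. Each locus is extended by `flank` (default
5000 nt) on both sides before the spliced alignment.

## The spliced aligner

`align_protein_to_locus()` computes an optimal *local* alignment under a state
scheme with codon match (BLOSUM62 over the translated codon), codon-sized
indels, 1-2 nt frameshifts, introns, and stop-codon traversal (recorded and
penalised, never terminating). Defaults: frameshift -15, intron open -10 with
+5 canonical GT..AG bonus, stop traversal -20, codon gap -14. Two numerical
choices deserve explanation:

* **Codon-gap cost (-14).** A stop codon can be "hidden" by deleting the
  residue and skipping the codon (one residue gap + one codon gap). With both
  gaps at -10 that evasion costs -20, exactly the stop-traversal penalty, so
  any adjacent substitution tips the optimum toward hiding real stops. At -14
  the evasion costs -28 and traversal always wins by a clear margin.
* **Tie-breaking.** Moves are evaluated in a fixed order (match/stop >
  frameshift > codon gaps > intron) with strict improvement required, and the
  column sweep keeps the leftmost solution: identical inputs always give
  identical tracebacks.

Introns open only between codons (phase-0); phase-1/2 introns are a declared
limitation, and the simulator plants phase-0 structures accordingly. The DP is
validated against an independent plain-R dynamic program on randomized
instances, which is itself validated against exhaustive path enumeration on
very small instances.

## Disruption calling

One record per in-frame stop inside aligned blocks and per frame-breaking
indel; consecutive indels within one codon merge to their net size (net
multiples of 3 vanish -- one mutational event, not two). Each record carries:

* `window_identity` -- amino-acid identity of aligned residues within 30 nt on
  each side (the event's own codon excluded);
* `boundary_distance` -- nt to the nearest inferred intron boundary;
* `support`/`total` -- worst-position read support over the event's footprint,
  padded by 6 nt on each side because indel placement inside repeats is
  ambiguous by up to a codon.

The reference terminal stop never counts: it lies beyond the last protein
residue, so a query stop aligned "at" it is simply outside the alignment.
Loci with coverage below `coverage_floor` (default 0.5, a declared stand-in
for manual removal of fragmentary alignments) are `unalignable` and excluded
from both counts.

## The filter cascade

Stage 1 (unitary status), in order: large gene families (label-based:
olfactory receptors, zinc fingers, vomeronasal receptors by default);
predicted or intronless-cDNA reference models; functional redundancy -- all
genome-wide hits away from the called locus are merged along colinear runs,
chained into "copies" by exact maximum-coverage non-overlapping subset
selection, and any copy covering >= `copy_cov` (default 0.8) of the protein
disqualifies the call; conserved genomic position against the synteny map
(>= 50% overlap with the mapped interval; genes missing from the map are
removed with a distinct logged sub-reason).

Stage 2 (false positives): (a) a single disruption leaving more than `trunc`
(default 0.9) of the protein intact, a disruption within `boundary_nt`
(default 10 nt -- the rule names the boundary but no distance, so one is
declared) of an intron boundary, or one in a low-identity window
(< `min_identity`, default 0.4) is voided; (b) a disruption is confirmed only
if >= `read_conf` (default 0.8) of reads at its site support it at depth >=
`min_depth` (default 5); unknown support passes with a logged warning, and the
rule can be disabled per species (real screens only have raw reads for some
assemblies); (c) reference models need TSL 1/2 or a CCDS assignment;
(d) calls whose only valid disruptions are exactly two frame-restoring
frameshifts are removed. Calls with >= 2 valid disruptions after (a)-(b) pass
the per-disruption rules automatically -- the automatable proxy for manual
multi-disruption review, flagged in the trail.

Every decision appends to the call's ordered filter trail; every removal has
exactly one primary reason; per-stage counts are non-increasing by
construction and are reported in cascade order.

## The relaxed-selection gate

A disrupted ORF may still be a polymorphism or an undetected artifact; genuine
losses evolve under relaxed constraint. For each surviving call, the
foreground CDS (aligned codons, disruptions excised) joins the reference CDS
and any intact orthologs from other screened species; proteins are aligned by
centre-star progressive alignment and back-translated (adequate below the
package's declared divergence ceiling of 0.3 substitutions/site -- the reason
a phylogeny-aware aligner is not re-implemented). Masking removes
gap/ambiguity columns with two flanking codons each side (6 bp rounded
outward to whole codons), removes low-quality fragments -- defined here,
since the classic tool leaves it parameterless, as 5-codon windows with mean
modal-codon conservation < 0.5 -- iterates to a fixed point (hence
idempotent), and drops groups shorter than 150 nt.

dN/dS uses ancestral codon states from joint codon-level parsimony (per-site
reconstruction can recombine states across lineages into codons that never
existed, scattering phantom substitutions across branches -- measurably
biasing the foreground/background contrast in small groups). Substitutions
are counted by pathway averaging with stop-codon paths excluded; sites are
kappa-weighted with mutations-to-stop excluded, matching the simulator's
state space; proportions receive a Jukes-Cantor correction. The selection
intensity is the closed-form exponent `k = ln(omega_fg) / ln(omega_bg)` of
the `omega_fg = omega_bg^k` parameterisation, with a nonparametric
codon-bootstrap probability of `k >= 1` reported as advisory information. The
gate retains a call iff `omega_fg > omega_bg` and `k < 1` -- significance is
deliberately not required, matching the screen this package models. With
`omega_bg >= 1` the exponent is undefined and the gate falls back to the
omega comparison alone (logged). Note that for `omega < 1` the two gate
conditions are mathematically equivalent, so near `k = 1` the decision is a
coin flip in estimation noise; the bootstrap p quantifies that.

Estimated `k` has a standard deviation of roughly 0.08 at 3000 codons on a
16-taxon tree with 0.05 substitutions/site branches, so single-replicate
recovery within +/- 0.15 is a ~2-sigma event: occasional seeds fall outside
(the suite's canonical seed does, for k = 0.5, and the acceptance test
reports it honestly).

## The synthetic world

`generate_reference()` builds multi-exon genes (ATG start, one terminal stop,
GT..AG phase-0 introns, no internal stops) with healthy annotation flags;
`evolve_query()` applies genome-wide divergence and realises a planted event
plan. Defaults state the benchmark world: 200 genes of 100-300 codons, 2-6
exons, divergence 0.05 substitutions/site, transition bias kappa = 2. Within
intact coding sequence, substitutions are synonymous-biased (non-synonymous
proposals accepted with probability `omega_intact` = 0.2, stops never), so
intactness is preserved while background dN/dS is realistic; disrupted genes
accept all non-stop changes (omega ~ 1, the relaxed regime the gate must
detect); splice dinucleotides, start and stop codons are protected so the
truth table stays exact.

Planted events: premature stops, 1-2 nt frameshifts, compensatory pairs
(realised as +size at the planned codon and -size 30 codons downstream),
assembly errors (a frameshift whose inserted bases get low read support),
duplicated genomic copies, intronless retrocopies, and diverged family
paralogs on a separate contig, plus annotation overrides (predicted /
intronless / TSL / CCDS / family labels) for reference-side artifact classes.
The generator's fate rule mirrors the cascade's own definitions: any
artifact-cause event or bad-annotation override makes a disrupted gene
`artifact_only`, as does a lone stop beyond 90% of the protein; benchmark
disruptions are planted >= 10 codons from exon boundaries because the
cascade itself distrusts boundary-adjacent disruptions and spliced aligners
can legitimately shift introns by a few codons. Synteny-mismatch artifacts
cannot be expressed in the event vocabulary (there is no translocation
event); that rule is exercised by constructed unit tests instead.

What a green benchmark does *not* establish: performance on real genomes with
repeat landscapes, GC heterogeneity, fragmented assemblies, alternative
isoforms, or non-phase-0 introns -- none of which the simulator emulates.

## Statistics

`fisher_two_sided()` uses the point-probability rule (tables as extreme as
observed by point probability), the convention that reproduces the published
two-sided values; `bh_fdr()` is step-up Benjamini-Hochberg; convergent-loss
overlap uses the upper-tail hypergeometric with the ortholog-universe size
`N` as a *required input* (published analyses rarely print it; this package
refuses to guess a default). Functional groups are keyword-defined over GO
term names with is_a ancestor closure only (part_of deliberately excluded --
the simplest defensible closure); a group is an *enriched functional group*
for a species when the Fisher FDR is below `fdr_alpha` against its own
non-pseudogene background *or* against the control species' pseudogene list
(the disjunctive definition). Both exact tests are verified against full
factorial enumeration for every table with N <= 40.

## Known limitations

* The search's empirical E-value is a decoy-based stand-in; very short or
  low-complexity proteins get conservative fits.
* Phase-1/2 introns, splice-site-loss, promoter loss and start-codon loss are
  out of vocabulary, as are selenocysteine readthrough codons.
* `k` is a closed-form analogue of likelihood-based selection-intensity
  estimates; it preserves the gate's decision variables, not published
  numerical `k` values.
* Proteins above ~5,000 aa are outside the aligner's intended envelope.
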