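---
title: "Mining olfactory receptor repertoires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining olfactory receptor repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`orminer` annotates olfactory receptor (OR) gene repertoires in genome
assemblies and characterizes their organization, phylogeny, selection
regime, motifs and expression. This vignette explains the model behind
each stage, the tunable parameters, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## The identification protocol

OR genes are intronless, single-exon, seven-transmembrane GPCR genes.
The annotation protocol therefore works directly on genomic DNA:

1. **Translated search.** Every contig is translated in all six reading
   frames and scanned with a panel of known OR proteins using
   Smith--Waterman local alignment (BLOSUM62, gap open 11 / extend 1; a
   gap of length $L$ costs $11 + L$). E-values follow the
   Karlin--Altschul form $E = K m n e^{-\lambda S}$ with $m$ the query
   length and $n$ the total translated length of all frames. The
   constants are fixed at the classic gapped-BLOSUM62 values
   ($K = 0.041$, $\lambda = 0.267$) rather than estimated per run:
   nothing downstream is sensitive to their exact values (the cutoff is
   a permissive $E \le 10$), and fixing them makes runs reproducible.
   There is deliberately *no* alignment-length floor: weak, short hits
   are retained so that fragmentary and decayed genes are not lost.
2. **Best-hit loci.** Hits on one contig and strand chain into a locus
   when their genomic gap is at most 5 kb. The chain gap is a
   compromise: OR coding sequences are about 1 kb, so the two or three
   HSPs into which a frameshift or premature stop splits a gene sit well
   within 5 kb, while tandem neighbours (planted at 10 kb spacing, and
   rarely closer in real clusters) stay separate. Per locus, the hit
   with the lowest e-value, then the longest alignment, then the highest
   bitscore, then the lexicographically smallest query id defines the
   best query; all tie-breaks are deterministic.
3. **ORF rescue.** In the reading frame of the locus's 5'-most best-query
   hit, the rescuer scans up to 1000 bp upstream and takes the most
   upstream in-frame `ATG` not preceded (in frame) by a stop codon --
   i.e. the start that maximizes the stop-free ORF; downstream it takes
   the nearest in-frame stop within 1000 bp. Scans clamp at contig
   edges, leaving `has_start`/`has_stop` unset -- this is how truncated
   genes are represented rather than a special case. Premature in-frame
   stops, and frame changes between chained hits of the best query, are
   recorded as disruptions; frameshifts are localized at the inter-hit
   junction because that is what a translated-search protocol can
   actually observe (base-level realignment is out of scope).
4. **Reciprocal filter.** Each candidate protein is aligned against the
   OR reference panel and a non-OR GPCR decoy panel; the side with the
   single best score labels it. Ties go to non-OR: discarding an
   ambiguous candidate is the conservative choice for repertoire counts.
5. **Three-way call.** Truncated if a terminus is missing -- checked
   *before* the pseudogene rule, so a truncated fragment with an
   internal stop is truncated, not a pseudogene (the truncation
   definition keys on missing termini irrespective of internal state);
   otherwise pseudogene if the model is at least 250 aa with
   disruptions; otherwise functional if at least 250 aa, intact, and
   with at least 7 predicted transmembrane segments. Intact sub-250-aa
   models are dropped (with a logged reason), not called truncated,
   because both the functional and pseudogene definitions share the
   250-aa floor. TM prediction is plain Kyte--Doolittle hydropathy
   (window 19, mean > 1.6, segments closer than 5 residues merged) with
   all three constants exposed in the configuration; the "at least 7"
   reading of the seven-TM requirement is a declared choice.

## Organization, groups, subfamilies

Genes more than 1 Mb apart fall in different clusters; the gap is
measured end-to-start between adjacent genes (a literal reading of
"gene sequences apart"). The per-chromosome summary counts functional
genes and pseudogenes only -- truncated models are retained in the GFF
but excluded from the table, mirroring how published repertoire tables
are laid out -- and percentages are integer, rounded half-up (12/49
gives 24, not 24.49).

Group assignment builds an unrooted neighbor-joining tree (Saitou--Nei,
via `ape::nj`) over the queries plus labeled references on protein
p-distances (mismatches over gap-free columns). The alignment feeding
the distances is a star alignment anchored on the longest *labeled
reference* -- queries can be truncated or frameshift-damaged, which
makes them unstable anchors -- with ends-free pairwise alignment so that
truncated sequences keep their register. Each query takes the group of
its nearest labeled leaf by tree path length ("closest known gene"),
with equidistant ties resolved to the smallest group label and flagged
by low support. Negative NJ branch lengths are clamped to zero with the
deficit moved to the sister branch, preserving path lengths through the
parent. Bootstrap support resamples alignment columns; the default is
100 replicates (config-raisable) to keep desk-scale runtimes, and the
reported value is the fraction of replicates that agree with the point
assignment. Assignments to the theta/kappa/lambda groups are flagged
non-OR. The self-assignment control -- every labeled reference, when
re-inserted as a query, must recover its own group -- runs in the test
suite and the acceptance script.

Subfamily clustering uses pairwise global identity with free terminal
gaps, with identities counted over alignment columns excluding
terminal-gap columns: gene models are length-heterogeneous, and
penalized terminal gaps would keep genuinely similar proteins below the
60% cutoff. Membership is single-linkage (connected components of the
at-least-cutoff graph): the published protocol says only that genes were
grouped by sequence identity, and single linkage is the weakest
assumption; complete linkage is available by flag. The family cutoff of
40% follows OR nomenclature convention and is an assumption -- only the
60% subfamily cutoff is prescribed. Cluster ids are named after the
smallest member gene id, which makes partitions invariant to input
order.

## Selection (dN/dS)

Per-group selection pressure is estimated with the Nei--Gojobori (1986)
counting method on pairwise codon alignments: per-codon synonymous site
fractions, multi-nucleotide codon differences averaged over all minimal
substitution paths (paths through stop codons excluded; if every path is
blocked, all paths are used with stop steps counted nonsynonymous), and
the Jukes--Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$,
with $p \ge 3/4$ flagged saturated. The group statistic is the mean over
pairs with a defined ratio ($d_S > 0$); single-sequence groups and
groups with no defined pair are excluded with a log message. This is a
deliberate, clearly-labeled counting-method stand-in for per-site
likelihood selection analyses: the downstream quantity is a per-group
average, which NG86 reproduces in regime (purifying vs neutral vs
positive), and per-site machinery would be out of proportion here.
Pseudogenes are excluded -- internal stops break the codon model.

The codon-evolution simulator proposes single-nucleotide changes,
rejects those creating stops, accepts synonymous changes always and
nonsynonymous ones with probability $\omega$, so the realized rate ratio
approximates the target. Parameter-recovery tests (500 codons, 10 pairs,
$\omega \in \{0.2, 0.5, 1.0\}$, tolerance $\pm 0.15$) and the
purifying-regime check (100 seeded replicates at $\omega = 0.2$, group
mean below 1 in at least 95%) run in the suite.

## Motifs, sequons, expression

Motif *discovery* is out of scope; the five conserved motifs ship as
configuration (exact consensus strings by default, degenerate patterns
and PWMs with log-odds thresholds also supported), and scanning reports
presence/absence and positions, which is all the downstream
pattern-frequency statistic needs. The N-glycosylation scanner is the
deterministic sequon rule N-X-S/T with X != P -- a declared stand-in for
neural-network predictors, and exactly reproducible. Expression
summaries compute FPKM from a fragment-count matrix with library totals
taken from the matrix itself (self-contained -- no external
mapped-reads figure), and call a gene expressed at mean FPKM >= 1 in
some stage and differential at fold change >= 2 between stages; both
thresholds are config-exposed assumptions, since no statistical test is
prescribed for this summary, and the output headers label the rule as a
fold-change stand-in.

## The synthetic genome: what it emulates, and what it does not

The generator's defaults *are* the validation conditions: 40 functional
genes, 12 pseudogenes (planted premature stops, 1-nt frameshifts, or
both), 8 edge-truncated genes and 10 non-OR GPCR decoys on 5 contigs of
1.6 Mb, arranged in 8 tandem clusters (2+2+2+1+1) with 10 kb
within-cluster spacing, one shared orientation per cluster, and a 1.2 Mb
inter-cluster gap (the megabase rule requires the planned gap to exceed
1 Mb). The subfamily plan nests a large 10-member subfamily and several
smaller ones (targets 70--85% within-subfamily identity, calibrated by
binary search against the package's own `pairwise_identity`), echoing
the skew of real repertoires. Background sequence is i.i.d. at GC 0.41 --
a typical teleost value; the source genome's base composition is not
published, so the default is a generic fish-like choice, not a
calibration. Planted proteins are built from a scaffold of seven
23-residue hydrophobic stretches separated by hydrophilic loops carrying
the five configured motifs and an N-X-S/T sequon, then reverse-translated;
coding sequences are inherited down the group-subfamily-member lineage
with a 10% synonymous resampling rate, so synonymous sites diverge
gradually (independent uniform codon choice per gene would saturate
synonymous distances and leave $d_S$ undefined).

Two generator details exist to make recovery *exactly* checkable. An
in-frame stop codon is planted immediately upstream of each intact
gene's ATG: real intergenic DNA is stop-rich, and the guard pins the
rescuer's "most upstream ATG before a stop" rule to the planted start,
so the rescued interval must equal the planted interval base-for-base.
And generated proteins carry methionine only at position 1 (the TM and
loop mutation alphabets exclude M), so an edge-truncated copy cannot
regain a spurious in-frame start during rescue.

What passing these tests shows is that the pipeline's logic is correct
under its own assumptions. What it does not show: robustness to introns
or split genes (OR models here are intronless by design), repeats and
low-complexity DNA, assembly artifacts, codon-usage bias, or query
panels far diverged from the target genes. Real-genome use should treat
the defaults as starting points, not validated settings.

## Numerical choices and degenerate inputs

* Smith--Waterman traceback breaks ties diagonal > up > left, and local
  alignments stop at score zero; scores are integers, so oracle
  comparisons are exact. The seeded search mode (exact 4-mer two-hit
  windows, the default) is a windowing strategy around the same exact
  DP; the exhaustive mode tiles frames in overlapping blocks. Both
  extract multiple HSPs per window by recursive splitting; the seeded
  mode may skip weak random-background hits that have no two-hit seed,
  which is verified not to affect planted-gene recall. The default is
  the seeded mode because full-frame traceback matrices on megabase
  contigs are prohibitively large, and the exhaustive tiling exists as
  the reference behaviour.
* Empty contigs translate to six empty tracks; codons containing N
  translate to X; an e-value cutoff of 0 returns no hits; proteins
  shorter than the hydropathy window predict zero TM segments.
* A rescue flank of 0 confines models to their hit interval; missing
  termini are encoded in flags, never as errors.
* Percentages in summary tables are integer half-up; motif-pattern
  percentages are two-decimal and sum to 100 within rounding.

## Problem sizes

The suite validates module behaviour on a small two-contig preset
(about 0.3 Mb, 14 planted genes) and runs the full default-scale genome
(8 Mb, 70 planted genes) once for the end-to-end recovery checks; the
acceptance script repeats the default-scale run from scratch. These
sizes were chosen so that every stage, including the quadratic
alignment steps, is exercised at a scale where exact ground-truth
checking is feasible.

## Known limitations

* Frameshifts are localized only to the inter-hit junction; codon-level
  repair ("conceptual translation" through a frameshift) is not
  attempted.
* Rescue does not stop at a neighbouring gene's hits; with flanks of
  1 kb and planted spacings of 10 kb this cannot collide, but unusually
  dense real clusters could require a smaller flank.
* The NJ group tree is a classification device, not a publication-grade
  phylogeny; maximum-likelihood tree building is explicitly out of
  scope.
* FPKM summaries start from a count matrix; read mapping and transcript
  assembly are upstream of this package.
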