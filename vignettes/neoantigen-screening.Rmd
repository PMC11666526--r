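---
title: "Neoantigen candidate screening: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoantigen candidate screening: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscreen)
```

## The screening problem

Somatic mutations in a tumor create proteins absent from normal tissue.
Short fragments of those proteins (8–11-mers) can be presented by MHC
class I molecules and recognised by CD8+ T cells, making them candidate
targets — neoantigens — for personalised immunotherapy. In a multifocal
tumor, candidates shared by several foci are more attractive targets than
private ones, because one peptide can cover more of the disease.

`neoscreen` implements the computational arm of such a screen for small
lung-adenocarcinoma-style cohorts: from per-focus somatic calls (MAF or
annotated VCF) to a ranked table of mutant/wild-type peptide pairs that
pass a binding filter, harmonized across several prediction algorithms,
and screened for multifocal sharing. Upstream read alignment, somatic
calling and HLA typing are out of scope — the pipeline starts from calls.

## The model, stage by stage

**Mutation landscape.** Variants carry a classification (missense,
nonsense, frameshift insertion/deletion, in-frame indel, splice site,
nonstop, silent). Silent calls are parsed but excluded from every tally,
burden and peptide computation. Single-base substitutions are collapsed
onto the pyrimidine reference (G>A reported as C>T, etc.) to give the
six-class spectrum. Genes are ranked by the number of samples carrying a
non-silent mutation, with total variant count and then the symbol as
tie-breaks; the cross-patient screen keeps genes mutated in *every*
patient with a single classification across the cohort. We interpret
"same type of mutation" as same classification rather than same
amino-acid change — both are computable, but the classification reading
is the weaker and therefore safer criterion.

**Burden.** Tumor mutational burden is

$$\mathrm{TMB} = \frac{\#\{\text{non-silent variants}\}}{\text{interrogated Mb}},$$

reported separately for SNV- and indel-derived burden (the two sum to the
total exactly). The interrogated-region size is a configuration value with
default 38 Mb, a typical human whole-exome capture; published analyses
rarely state their denominator, so it is explicit here. Tumor neoantigen
burden (TNB) is defined operationally: the number of distinct variants in a
sample yielding at least one peptide that passes the high-binder filter.
By construction TNB never exceeds the non-silent variant count.

**Peptide enumeration.** Each coding variant is applied to its transcript
CDS and re-translated. Substitutions give a single altered residue;
in-frame indels a short altered span; frameshifts are re-translated from
the shifted codon to the first novel stop (to the CDS end, flagged, if no
stop appears). All windows of length 8–11 overlapping at least one altered
residue become mutant peptides; the wild-type counterpart is the window of
the unmutated protein at the *same start coordinate*. For frameshifts the
two may share no residues — equal-length but unrelated pairs are expected
and legitimate. Peptides containing stop or ambiguous residues, and mutant
windows identical to their wild-type window, are dropped before scoring.
Duplicates are removed at one pair per (gene, mutant peptide), merging the
foci sets and keeping the best-scoring occurrence when scores are
attached. Splice-site variants yield no peptides; strand handling is
restricted to plus-strand toy transcripts, a documented limitation of the
synthetic substrate rather than of the method.

**The binding filter.** A mutant peptide is a *high binder* when its
predicted IC50 is strictly below 500 nM **and** strictly below the IC50 of
its wild-type counterpart, for at least one patient allele. Both
inequalities are strict: a peptide at exactly 500 nM fails. The
first-round filter uses a single affinity predictor (NetMHCpan-style
records by preference); the other algorithms enter only the second-round
comparison below. Pairs with a missing wild-type or mutant score are
skipped with a warning, never silently dropped.

**Score harmonization.** Affinity predictors output a binding
concentration $a$ (nM) where higher means weaker. It is transformed to

$$b = \frac{1}{\log_{10} a},$$

which increases with affinity; eluted-ligand and SYFPEITHI scores already
do and pass through unchanged. The logarithm base is configurable and
cancels in every rank-based use; base 10 is the default because the
pre-scores are concentrations spanning decades. Values of $a \le 1.01$
would make $b$ blow up and are clamped to $1.01$ with a warning — real
predictors do emit sub-nanomolar affinities. A fold change
$\mathrm{FC} = a_{\mathrm{wt}} / a_{\mathrm{mut}}$ summarises the
mutant-versus-wild-type affinity shift (values above 1 mean the mutation
improved binding). Each score column is then min–max rescaled onto
$[1, 20]$:

$$c = \frac{b - \min b}{\max b - \min b} \times 19 + 1,$$

so every algorithm's column has minimum 1 and maximum 20 within the
ranked batch; a degenerate batch (all equal) maps to the midpoint 10.5.

**Consensus and sharing.** The top 30 candidates by mutant IC50 get the
per-algorithm $c$ columns plus the fold-change column, and a consensus
score per pair — by default the unweighted mean of the available $c$
values (a rank-sum alternative is available). No algorithm weighting is
attempted: the original selection also weighed wet-lab practicalities
(synthesis difficulty, solubility) that are deliberately not modelled.
The multifocal screen finally keeps candidates present in at least
`min_foci` foci (default 2).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ic50_threshold` | 500 | nM | the conventional high-binder cutoff |
| `lengths` | 8–11 | residues | MHC class I ligand lengths |
| `top_n` | 30 | pairs | first-round candidate budget |
| `min_foci` | 2 | foci | multifocal sharing criterion |
| `interrogated_mb` | 38 | Mb | typical exome capture size |
| `log_base` | 10 | — | cancels in ranks; decade-scaled scores |
| `eps` (clamp) | 0.01 | nM above 1 | keeps $1/\log a$ finite |

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the study design the package is
calibrated against: 4 patients, the fourth multifocal with two
pre-invasive and two invasive foci; missense-dominant class weights
(0.754 missense, 0.088 frameshift-deletion, 0.056 in-frame-deletion,
0.033 frameshift-insertion, remainder split over the other coding
classes, silent off by default since the emulated proportions exclude
silent calls); ~50 mutations per focus; 30% trunk mutations shared by
all foci of a patient; recurrent genes (MUC16, EGFR, RBM10) boosted
20-fold in mutation probability; a 4:1 transition bias so C>T and T>C
dominate the six-class spectrum; and a 10% per-variant chance of
carrying a high-binder peptide. One global RNG is seeded per run, so
every file and ground-truth label is reconstructible from the seed.

`simulate_binding()` plants binders per variant: a planted variant's
mutant windows get IC50 ~ Uniform(10, 450) nM with wild-type IC50 1.5–10×
higher (both filter conditions hold by construction); all other peptides
draw above 600 nM and fail the threshold outright. Scores are assigned
per unique peptide sequence — predictors score sequences, not pairs — with
a constraint pass for the rare peptide that is one pair's mutant and
another's wild type. Eluted-ligand and SYFPEITHI columns are generated
rank-concordant with the affinities plus noise.

The generator does **not** model trinucleotide mutational signatures,
copy number, tumor purity or clonality, splice-site consequences, minus
strands, proteasomal processing, or class II ligand enumeration (class II
TNB is computable only from externally supplied calls). Passing tests
therefore demonstrate the pipeline's internal correctness — parameter
recovery, filter logic, ranking contracts — on cohorts whose generative
assumptions are much simpler than real exomes; they do not validate
binding predictions or immunogenicity on real data.

## Numerical choices and degenerate inputs

* Ties in gene ranking break by total variant count, then symbol; ties in
  candidate ranking break by mutant IC50, then pair id — all orderings are
  deterministic.
* A degenerate rescaling batch maps to 10.5, the midpoint of the target
  range; an empty batch is an error.
* Empty variant tables, empty predictor tables, and cohorts with zero high
  binders all return empty, well-formed objects rather than failing.
* Frameshifts with no downstream stop translate to the CDS end and are
  flagged (`runthrough`).
* The toy predictor is a deterministic hash-plus-anchor model
  (`log10 IC50 = 4.2 − 1.6·anchors + 0.5·u`); it exists so the pipeline
  runs end-to-end offline and is not a trained binding model.

## Problem sizes used in the checks

The test-suite simulations use cohorts of roughly 300–5000 variants:
class-weight recovery at ~5000 draws (3 binomial SE), TNB recovery at
~800–2000 variants, the TMB–TNB correlation across 10 single-focus
cohorts spanning a 10× burden range, and the pre-invasive/invasive
equality check across 10 replicate 8-focus cohorts (at least 7 of 10
t-tests non-significant — a formulation that is fair under the null
rather than dependent on one seeded p-value). The planted-binder recall
check screens exactly three missense variants with 9-mer windows so the
planted set (≤ 27 pairs) always fits the top-30 budget.

## Known limitations

Beyond the generator's simplifications above: genomic-to-CDS mapping
supports only a minimal transcript-relative convention (one transcript
per gene, plus strand); the consensus is an unweighted mean, which treats
algorithms as exchangeable; and the package deliberately stops at ranked
candidates — expression filters, immunogenicity prediction and any
wet-lab validation are outside its scope.
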