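---
title: "Counter-selective virtual screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counter-selective virtual screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(counterscreen)
```

## The screening problem

P-glycoprotein (P-gp, ABCB1) is an ATP-powered efflux pump whose
overexpression makes cancer cells resistant to chemically diverse
chemotherapeutics. Classical P-gp inhibitors bind the transmembrane drug
binding domains (DBDs) and tend to be transport substrates themselves: the
pump exports its own inhibitor, driving up the required dose. The
alternative pursued here is *counter-selection*: search for molecules
predicted to bind the cytoplasmic nucleotide binding domains (NBDs)
tightly while binding the DBDs weakly, across several conformations of the
transport cycle.

`counterscreen` implements the computational side of that campaign — the
library preparation, diversity handling, docking-output bookkeeping, and
the ratio statistic used for ranking — together with the arithmetic of the
wet-lab assays used to validate hits (MTT re-sensitization, LC-MS/MS
relative accumulation, daunorubicin retention). Docking itself, molecular
dynamics, and QSAR servers are external: the package only emits their
inputs and parses their outputs.

## The counter-selection statistic

A docking engine reports an estimated binding free energy $\Delta G$
(kcal/mol) per ligand pose. Per ligand and receptor box we keep the best
(lowest) energy and convert it to an estimated dissociation constant at
$T = 310\,\mathrm{K}$ through

$$\Delta G = RT \ln K_D , \qquad
  K_D = \exp\!\left(\frac{\Delta G}{RT}\right),$$

with $R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and $K_D$ in molar
units relative to a 1 M standard state. These values are never treated as
affinity measurements; they only enter the per-conformation ratio

$$\rho = \frac{K_D^{\mathrm{DBD}}}{K_D^{\mathrm{NBD}}}
       = \exp\!\left(\frac{\Delta G^{\mathrm{DBD}} -
         \Delta G^{\mathrm{NBD}}}{RT}\right),$$

which is $>1$ exactly when the NBD binding is predicted tighter, and which
depends only on the *difference* of the two energies (so any systematic
offset of a docking run cancels). With several receptor boxes per domain
and conformation, each side of a ratio uses the best energy across that
side's boxes.

**Aggregation across conformations.** When a manifest pairs DBD and NBD
boxes in several conformations, a ligand has one ratio per pair and the
pairs must be reduced to one ranking score. Two defensible policies exist
and both are implemented: the *worst pair* (`min`, the default), under
which a ligand must prefer the NBDs in every conformation, and the
geometric mean. We default to `min` because the screen's purpose is to
exclude molecules that interact strongly with the DBDs in *any*
conformation they encounter during transport; the geometric mean can hide
one bad conformation behind several good ones. A ligand with no usable
result on one side of a pair scores zero under `min` (dropped from
contention, counted in the output) — conservative, because an unmeasured
DBD interaction cannot be ruled out.

## Library preparation and diversity

Drug-likeness filtering keeps records with 150 < MW < 500 g/mol,
logP < 5, TPSA < 150 Å², H-bond donors < 5, acceptors < 10, rotatable
bonds ≤ 7, and no aldehyde or thiol group. All bounds are strict
inequalities except rotatable bonds, which is inclusive at 7; boundary
molecules (MW exactly 500) are rejected. Descriptor *definitions* follow
the calculator, which is a pluggable contract (`obabel_calculator()` by
default, backed by Open Babel): rotatable-bond conventions and TPSA
parameterisations differ between toolkits, and pinning the filter to one
calculator keeps the decision reproducible without pretending the bounds
are calculator-independent. Only aldehydes and thiols are excluded as
reactive groups; other electrophiles are left to the user's own filters.

Diversity subsets use the *leader* (sphere-exclusion) construction:
ligands are offered in library order (or a seeded permutation) and
retained iff their Tanimoto similarity to every previously retained ligand
is at most the cutoff; excluded ligands are assigned to the first retained
ligand that exceeds it. This yields two checkable invariants — no two
retained ligands above the cutoff, every excluded ligand above the cutoff
to its representative — which the test suite verifies by exhaustive
pairwise comparison. A "90 % diversity set" is interpreted as sphere
exclusion at cutoff 0.90; the alternative reading ("a set containing 90 %
of the diversity") has no testable construction and is not implemented.

Fingerprints default to Open Babel's FP2, a hashed linear-fragment
(path) fingerprint of 1024 bits. The scheme is declared on every
fingerprint set and mixing schemes is an error. Two conventions are fixed
deliberately: similarity of two all-zero fingerprints is defined as 1
(featureless molecules are mutually redundant, so only one survives a
subset), and similarity-band endpoints in `similarity_expand()` are
inclusive on both sides, with the query itself always excluded.

The two-round screen (`iterate_screen()`) docks the diversity subset,
keeps the top 100 by aggregated ratio, expands those hits into their
0.70–0.99 similarity neighbourhood in the full library, docks the new
molecules, and merges the rounds (deduplicated by ligand, best aggregate
wins). Ties in any ranking break lexicographically by ligand id, so
rankings are invariant to input permutation.

## Assay analysis

**MTT re-sensitization.** Percent survival is
$100 \times A_{\mathrm{well}} / \overline{A}_{\mathrm{control}}$ against
the vehicle control. A compound is a re-sensitizer when co-treatment with
the chemotherapeutic lowers survival by at least 30 *percentage points*
relative to the chemotherapeutic alone — percentage points rather than
relative percent, because both percentages share the same vehicle
denominator; the bound is inclusive at 30. The threshold is a parameter.

**LC-MS/MS substrate calls.** Each sample's analyte peak area is divided
by the internal-standard peak area and by the lysate protein content
(mg/mL); triplicate normalized ratios give a mean ± SD per compound,
condition (± tariquidar) and trial. Significance uses Student's t with
*pooled* variance and $n_1+n_2-2$ degrees of freedom, computable from
summary statistics alone — this is the variant that reproduces the
reference table's printed p-values from its printed means and SDs, which
the test suite checks to one significant figure for all 19 reported
values. A compound is called a likely transport substrate when any trial
shows $p<0.05$ *and* higher accumulation with the pump inhibited
(direction rule); trials with analyte below quantification are
indeterminate and never produce a substrate call. Two-sided p-values are
capped at 1; a printed "> 1" is read as 1. No multiple-testing correction
is applied, matching the single-compound decision procedure the assays
implement.

**Daunorubicin accumulation.** The fold change is the mean fluorescence
of compound-plus-daunorubicin wells over daunorubicin-alone wells, tested
with the same pooled t. Background fluorescence is assumed
pre-subtracted; an optional blank argument is provided.

## Synthetic data: what it emulates and what it does not

The generators exist so every pipeline stage can be tested end to end,
deterministically, without external engines.

`gen_ligand_library()` builds clustered SMILES libraries from a fragment
grammar: each cluster is a scaffold of five directly bonded heterocyclic
rings plus satellites that differ by one or two small ring substituents
(halogen, methyl, hydroxyl, amino). Because a satellite's path
fingerprint strictly contains its representative's, the
representative–satellite similarity is `bits(scaffold) /
(bits(scaffold) + bits(substituent))`, which the generator steers toward
the requested `within_cluster_similarity` by choosing among candidate
substitutions; targets above ~0.96 are rejected as infeasible for
drug-sized molecules under FP2. Scaffolds are screened against descriptor
bounds with headroom for the heaviest substituent so members land inside
the drug-likeness window unless deliberately generated as violators.
These molecules are chemically valid but synthetic: they do not model
real vendor libraries' functional-group distributions, tautomers or
protonation states, so passing tests demonstrate algorithmic
correctness, not chemical realism.

`planted_landscape()`/`mock_dock()` replace the docking engine with
additive ground truth: energy = domain-class base + per-ligand NBD offset
+ Gaussian noise, with the noise drawn once per ligand–target pair so
repeated docking is consistent across rounds. The defaults used in the
recovery experiment are −7 kcal/mol base energies on both domains, a −3
kcal/mol planted NBD offset (a strong but docking-plausible preference,
giving a noiseless ratio of ≈130), and 0.5 kcal/mol noise, comparable to
docking rescoring variability. This is an abstraction for pipeline
testing — no force-field realism is intended.

`gen_assay_data()` draws Gaussian replicates around the group means the
ground truth implies (multiplicative noise at a set CV, default 5 %,
matching the mean ± SD reporting convention of plate and LC-MS/MS
assays), with resistant-cell chemo-only survival at 90 % and a 50-point
inhibitor effect, well clear of the 30-point decision bound.

## Problem sizes and numerical choices

The planted-recovery experiment uses a 1,000-ligand library in 50
clusters with 20 planted NBD-preferrers — ten cluster representatives
(reachable in round 1) and their nearest satellites (reachable only
through round-2 expansion) — which exercises both rounds while keeping a
full run to seconds on one core. The real campaign this mirrors screened
~10⁵–10⁶ molecules over 14 boxes; the statistic and control flow are
identical, only the scale differs.

Energies are stored at full precision; fixture writers round to 0.1
kcal/mol only in the Vina-style display dialects (and to 10⁻⁴ in the
score tables), with write–parse–write cycles byte-identical. The
`kd_from_dg()`/`ratio_score()` pair inverts $\Delta G = RT\ln K_D$ to
machine precision. Zero-variance t-tests are defined explicitly (equal
means: $t=0, p=1$; unequal: $p=0$ with a warning) rather than left to
produce NaN.

## Known limitations

* Protonation-state assignment (done at pH 7 by conversion tools in a
  real campaign) is not re-implemented; structures are taken as given.
* The sphere-exclusion subset depends on offer order; the order (and any
  seed) is recorded in the result, but no order-free diversity picker
  (MaxMin, k-medoids) is provided.
* Substrate calls from two or three trials have the power of n = 3
  triplicates; the classification reproduces the reference decisions but
  is not a substitute for dose–response transport assays.
* The package ranks ligands by estimated-ratio only; final compound
  selection in a real campaign additionally used docking-pose inspection
  and external QSAR predictions, which are out of scope here.
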