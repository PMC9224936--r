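---
title: "Screening MAG proteomes for Mn-oxidizing multicopper oxidases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening MAG proteomes for Mn-oxidizing multicopper oxidases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcoscreen)
```

## The problem

Bacterial Mn(II) oxidation is largely enzymatic, and the best-characterized
catalysts are multicopper oxidases (MCOs) such as moxA, mcoA and mnxG. An
MCO coordinates at least four copper atoms at conserved centres — the T1
(blue copper) site and the T2/T3a/T3b trinuclear cluster — through specific
histidine and cysteine ligands, with a variable axial position (commonly
Met, sometimes Leu/Phe). When metagenome-assembled genomes (MAGs) are
recovered from an environment such as a Mn-crust-forming hot spring, a
natural question is which MAGs encode plausible Mn-oxidizing MCOs.

`mcoscreen` implements that call as a four-criterion screen over predicted
proteins. A candidate is reported as a putative Mn-oxidizing gene only if it

1. shows **homology** to a known Mn-oxidizing gene — best-hit percent
   identity strictly greater than a threshold (default 30%);
2. is **domain-compatible** — scores significantly against a profile built
   from the known genes, relative to a composition-matched permutation null;
3. **conserves all four copper-binding centres** (T1, T2, T3a, T3b)
   transferred from its assigned reference by global alignment; and
4. falls **in the same clade** as the assigned known gene in a
   neighbor-joining tree, with no negative reference (an MCO without
   Mn-oxidation evidence) inside that clade.

A MAG "possesses a putative Mn-oxidizing gene" when at least one of its
candidates passes all four criteria.

## Operationalizing the criteria

The published form of this screen leans on external tools and databases
(BLASTP, HMMER against Pfam-A, MAFFT/trimAl/RAxML). This package makes the
whole pipeline self-contained and testable; each stage is an in-package
method chosen to preserve the *decision semantics* of the original:

* **Criterion 1 (homology).** "Homology" is operationalized as percent
  identity of the best Smith–Waterman local alignment under BLOSUM62 with
  affine gaps (open 11, extend 1 — classic protein-search defaults). The
  identity denominator includes gap columns (the convention of common
  search tools); a gap-free-denominator variant is also reported on every
  alignment object. The threshold is *strict*: exactly 30.0% fails. The
  winning reference becomes the candidate's "assigned known Mn-oxidizing
  gene", reused by criteria 3 and 4. No e-value is computed: e-values are
  database-scaled and meaningless without the original search space, so
  the identity cut carries the criterion alone.

* **Criterion 2 (domain compatibility).** An external domain database
  cannot be bundled, so the domain check is a position-specific scoring
  matrix (PSSM) derived from the positive references themselves: each
  reference is globally aligned to the longest one (the anchor), per-column
  residue counts become log-odds scores
  $s_a = \log\frac{(c_a + \tau b_a)/(n + \tau)}{b_a}$ with pseudocount
  $\tau = 1$ and BLOSUM62 marginal background $b$, and columns gapped in
  more than half the references are dropped. A candidate's score is
  compared with `n_perm = 999` uniform residue shuffles of itself — a
  length- and composition-preserving null — giving the add-one empirical
  p-value $p = (1+k)/(1+n_\mathrm{perm})$. The default significance level
  `alpha = 0.005` is deliberately conservative; the original 1e-5 e-value
  cut-off is not transferable for the reason above. Each candidate's null
  is seeded from the run seed plus a hash of the candidate id, so one
  candidate's p-value never depends on which other candidates are screened.

* **Criterion 3 (copper-binding sites).** Site positions annotated on the
  assigned reference are transferred through the global alignment.
  Conservation is exact membership in the annotated allowed set — the
  strictest defensible reading of "preservation" absent any published
  tolerance — with axial-position variability expressed as multi-letter
  allowed sets (e.g. `MLF`) in the reference table rather than in code. The
  criterion fails closed: a reference position landing in a gap column is
  unmapped (a gapped-out ligand cannot bind copper), an `X` never
  demonstrates conservation, and a reference lacking one of the four labels
  cannot support a pass.

* **Criterion 4 (co-clade placement).** Distances are Poisson-corrected
  mismatch fractions $-\ln(1-p)$ from pairwise global alignments; the tree
  is Saitou–Nei neighbor-joining; the root is the midpoint of the edge
  separating the outgroup references. "Same clade" is formalized — the
  source procedure leaves it operational — as: the leaf set of the most
  recent common ancestor of candidate and assigned gene contains no
  NEGATIVE reference. Maximum-likelihood inference with rate heterogeneity
  and bootstrap support was deliberately not reproduced: the criterion
  consumes only a topology, NJ is consistent on additive distances (a
  property the test suite verifies exhaustively at 5 leaves and by
  simulation at 6–8), and clade calls are therefore point estimates.

## Numerical and algorithmic choices

* Gap cost: a run of length $L$ costs $\mathrm{open} + L\cdot\mathrm{extend}$
  (so one gap under 11/1 costs 12), matching NCBI semantics; the alignment
  kernel's scores are cross-checked in the tests against both an
  exhaustive-enumeration oracle and an independent library implementation.
* Co-optimal alignments are resolved deterministically: residue pair over
  deletion over insertion; for local alignment, the best cell with the
  smallest query then subject index. Identical inputs and seed give
  byte-identical report files.
* `X` scores 0 against every residue and never satisfies a site.
* A local alignment may be empty (score 0) when no pairing is favourable.
* NJ pair selection breaks Q-criterion ties by the lexicographically
  smallest cluster-label pair; negative branch-length estimates are clamped
  to zero with the deficit shifted to the sibling branch, preserving the
  joined pair's path length. Saturated distances ($p \to 1$) are capped at
  10 substitutions/site.
* Candidate leaves are prefixed `Q|` in the tree to avoid collisions with
  reference ids.
* Criteria are evaluated in order 1→4 and short-circuit: stages after the
  first failure are reported `NOT_EVALUATED`, and only candidates surviving
  criteria 1–3 enter the (single, per-run) tree. One joint tree per run
  means a candidate's criterion-4 outcome can in principle depend on which
  other candidates survived; criteria 1–3 are candidate-local by
  construction.

## The synthetic benchmark

No sequence data at desk scale accompanies the source study, so the
package ships a generator (`synth_spec()`, `generate_synthetic()`) that
builds a fully labelled benchmark family:

* an ancestor of 300 residues drawn from the BLOSUM62 background, with ten
  annotated ligand positions (four T1 — His/Cys/His/Met, and His pairs for
  T2/T3a/T3b) spaced at least 5 residues apart;
* three POSITIVE references at 10% divergence from the ancestor, wearing
  the names moxA/mcoA/mnxG and their locus ids (CAJ19378, ABY98562,
  PputGB1_2447) **as labels only — the sequences are synthetic**, not the
  real loci; two NEGATIVE references at 55% divergence with ablated
  ligands, modelling a distinct MCO subfamily without Mn-oxidation
  evidence (negatives must be clearly outside the positive radiation for a
  clade criterion to be meaningful at all); one random OUTGROUP;
* candidates: true positives evolved at 20% per-site substitution from a
  specific reference lineage (as a real MAG homolog descends from a real
  gene family, not from an abstract ancestor), site-ablated decoys (every
  ligand mutated to Ala), distant homologs at 80% substitution, and
  composition-matched shuffles, assigned round-robin to MAG labels.

Substitutions are drawn from BLOSUM62-conditional frequencies
($P(b\,|\,a) \propto b_b\, 2^{S(a,b)/2}$), so identity decays realistically
and a "substitution" can silently redraw the same residue; at rate $r$ the
expected fraction of changed positions is $r(1-m)$ with $m$ the
self-substitution mass (about 0.3). A consequence worth stating plainly:
at 80% substitution the distant homologs retain roughly 45% best-hit local
identity — genuine homology is hard to erase — so they typically *pass* the
homology criterion and are rejected at the copper-site criterion instead
(each of ten unfrozen ligands survives with probability ≈ 0.5, so all ten
survive with probability ≈ 0.001).

What the generator does **not** emulate: indels and domain rearrangements,
fragmented ORFs at contig edges, compositional bias of real proteomes,
contamination across bins, and within-family rate heterogeneity. Passing
the benchmark therefore demonstrates that the pipeline's logic and
arithmetic are sound under its stated model, not that the thresholds are
optimal for any particular environment.

## Problem sizes used by the test suite

The shipped tests exercise: the alignment kernel against exhaustive
enumeration on 200 random pairs of length ≤ 7 over a 4-letter alphabet;
NJ recovery on all 15 labelled 5-leaf topologies and 100 random additive
matrices with 5–8 leaves; clade queries against brute-force enumeration on
50 random trees of up to 16 leaves; criterion-3 separation on 25 positives
and 25 ablated decoys; a full screen on a 100-candidate, 10-MAG benchmark
(sensitivity ≥ 0.9 required, zero passes among shuffled and ablated
decoys, flagged MAGs exactly the planted ones); permutation-null
calibration on 200 unrelated candidates (pass rate ≤ 2% at alpha = 0.005);
and byte-level determinism of the output files. `scripts/acceptance.R`
recomputes the headline numbers from scratch at the same scales.

## Known limitations

* Percent identity is computed on the best local alignment (HSP), not over
  full length; very long candidates with a short conserved stretch can
  clear criterion 1 on a small fraction of their length. Criteria 2–4
  guard against the consequences.
* The PSSM stands in for a curated domain model; it tests compatibility
  with the packaged reference family only, not membership in any wider
  cupredoxin clan.
* Clade calls carry no support values; borderline placements flip with
  tree noise rather than being flagged as uncertain.
* The screen targets the MCO family only. Heme-peroxidase (AHP-type)
  Mn oxidases would need their own reference set and site definitions.
* The isotope utility evaluates delta notation only; instrument
  calibration and drift correction are out of scope.
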