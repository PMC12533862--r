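---
title: "Post-docking triage of a repurposing screen: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-docking triage of a repurposing screen: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DockTriage)
```

## The problem

Structure-based drug repurposing screens against a membrane transporter
such as SGLT2 (the renal sodium–glucose cotransporter targeted by the
gliflozin drugs) produce three kinds of downstream analysis work that are
usually done with ad hoc scripts:

1. **Method benchmarking.** Before screening, the docking method is chosen
   by re-docking a reference inhibitor (here empagliflozin) and measuring
   how far the docked pose lands from the crystallographic one. The right
   metric is a *symmetry-corrected, superposition-free* RMSD: chemically
   equivalent atoms (a phenyl ring read in either direction, a rotated
   ring) must not inflate the deviation, and the poses already share the
   receptor frame, so no fitting is applied.
2. **Pose triage.** Docked poses are scored against the binding-site
   residues known to engage the reference inhibitor — close contacts at
   5 Å and hydrogen bonds — and a ranked library is reduced to a handful
   of candidates using an enrichment check over known actives, an
   interaction gate, and a clinical-suitability flag.
3. **MD validation.** Each candidate pose is run in short replicate
   molecular-dynamics simulations; the ligand-RMSD traces are censored at
   an escape threshold and summarised into one stability statistic per
   compound, which ranks the final table.

DockTriage implements all three layers as a tested, reusable package, with
seeded generators that fabricate every input with known ground truth.

## Symmetry-corrected RMSD

Two poses of the same molecule are compared over *all* element- and
bond-preserving bijections of their heavy atoms (graph isomorphisms),
taking the minimum of

$$\mathrm{RMSD}(\sigma) = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n}
  \lVert a_i - b_{\sigma(i)}\rVert^2}$$

over mappings $\sigma$. Design choices, each of which is a genuine fork:

* **Heavy atoms only.** Hydrogens are kept on read but excluded from the
  comparison — their placement is a force-field artefact in docking
  output.
* **Connectivity + element only.** Bond orders are ignored for the
  isomorphism: docking formats disagree on order assignment far more often
  than on connectivity.
* **No superposition.** Both poses are taken in the receptor frame; a
  Kabsch fit would hide genuine placement error.
* **Backtracking with pruning.** Candidates are filtered by element and
  degree and checked incrementally against previously mapped neighbours.
  The enumeration is capped (default 100,000 mappings) so pathological
  symmetry fails loudly rather than hanging. Candidates are tried in
  index order, making the output deterministic and lexicographic.

The test suite checks the search *exactly* against an independent
exhaustive-permutation oracle on random molecules of up to 8 heavy atoms
(the oracle enumerates per-element permutations and filters by adjacency;
it shares no code with the search).

```{r}
ring <- makeSymmetricLigand("ring6", seed = 1)$graph
length(enumerateMappings(ring, ring))   # dihedral group of benzene
```

## Interaction scoring

A residue is in **close contact** when the minimum heavy-atom distance to
the ligand is at most 5 Å — the same distance used to define the nine
key residues of the SGLT2 gliflozin site (ASN 75, HIS 80, THR 87, PHE 98,
GLU 99, SER 287, TYR 290, LYS 321, GLN 457; shipped as a packaged
fixture). "van der Waals contact" is deliberately operationalised as this
distance rule rather than a radii-sum criterion, because the 5 Å
definition is the one the screen itself is built on.

**Hydrogen bonds** use configurable geometric gates: donor–acceptor
≤ 3.5 Å, hydrogen–acceptor ≤ 2.5 Å, donor–hydrogen–acceptor angle
≥ 120°; N and O are donors when they carry a hydrogen, acceptors always.
These geometry defaults follow common structural practice and are *not*
load-bearing: the synthetic pockets plant ideal geometries (1.9 Å H···A,
170°) well inside any reasonable setting. When a pair offers no explicit
hydrogen to evaluate on either side (typical for crystallographic
receptors), the criterion degrades to the donor–acceptor distance gate
alone — but a pair whose explicit-hydrogen geometry was evaluated and
failed is never rescued by this fallback.

The **key-residue score** is $\sum_r w_{\mathrm{hb}}[r\ \mathrm{H\!-\!bonded}]
+ w_{\mathrm{ct}}[r\ \mathrm{contact\ only}]$ with defaults
$w_{\mathrm{hb}} = 2$, $w_{\mathrm{ct}} = 1$. The weights are exposed as
configuration because no published formula exists for them; the
**overlap** — the fraction of key residues engaged at all, which is
weight-free — is the primary triage quantity, and nothing in the
acceptance checks depends on the weighting.

## Screen triage

Ranking is ascending in docking score by default (lower-is-better,
matching empirical docking score conventions), with lexicographic id
tie-breaks. The top fraction $f$ of $N$ compounds is a bin of
$\max(1, \lfloor fN + 0.5\rfloor)$ (round-half-up): the top 1 % of 877
compounds is a bin of 9. The enrichment factor is the standard

$$EF_f = \frac{n_a / N_{\mathrm{top}}}{N_{\mathrm{actives}} / N}.$$

With the four licensed gliflozins inside the top-1 % bin of an
877-compound ranking this gives $877/9 \approx 97.44$; the published
figure of 97.1 for the same configuration is not exactly reproducible by
this formula for any integer bin size, so it is treated as a lower bound
rather than reverse-engineered. Candidate selection applies the gates in
flowchart order — score, overlap, clinical inclusion — and records, per
rejected compound, the first gate that fired. The clinical gate is a
user-supplied boolean column: in the original workflow it was a manual
judgment (route of administration, prescription frequency), not something
a structure pipeline should compute.

## MD stability statistic

Per replicate: the first frame whose RMSD strictly exceeds 5.5 Å (the
escape threshold above which a pose is considered non-binding) censors
the series — that frame and all later ones are assigned 10 Å. Censoring
is applied *forward* from the crossing rather than to the whole
replicate: the published description ("simulations exceeding this were
assigned 10 Å") does not specify scope, forward censoring preserves the
pre-escape signal, and both readings produce identical ranking statistics
whenever the escape precedes the ranking window; a config flag enables
whole-replicate censoring. Per compound: the pointwise median across the
three replicates (mean-of-central-pair for even counts), then the median
over the closed 9–10 ns window — the last nanosecond of a 10 ns
simulation — is the ranking statistic. A window median strictly below
5.5 Å classifies the pose as bound; exactly 5.5 Å classifies as unbound
(the threshold is described as the value *above* which poses are
non-binding, so binding requires strictly below; the boundary case is a
measure-zero event in practice).

Time series are ingested as precomputed RMSD tables (XVG or CSV);
computing per-frame ligand RMSD from raw trajectories — including whether
the protein is superposed first and whether symmetry correction is applied
per frame — belongs to the upstream simulation tooling and is out of
scope here. Values in nm are converted to Å at the read boundary, since
every threshold in the pipeline is in Å.

## Synthetic data: what it emulates, what it does not

The generators fabricate each input family under a fixed seed, recording
ground truth by construction:

* **Pockets** (`makePocketFixture`): interaction sites spaced 3 Å apart
  along a carbon-chain ligand; contact residues planted at 4.8 Å,
  H-bond residues with ideal 1.9 Å / 170° geometry, unplanted key
  residues and decoys beyond 7 Å; ±0.02 Å seeded jitter, small against
  every margin. Geometry, not chemistry: residues are three-atom stubs and
  the ligand is not a drug-like molecule, so these fixtures validate the
  *measurement* (distances, angles, counting), not docking realism.
* **Ligand graphs** (`makeSymmetricLigand`): a C–N–O chain (1
  automorphism), a benzene-like six-ring (12), and a pyridine-like ring
  (2) — closed-form symmetry groups for the mapping machinery.
* **Trajectories** (`makeTrajectory`): 1000 frames at 0.01 ns (a 10 ns
  run, mirroring the three-replicate 10 ns protocol). Stable traces are
  an AR(1) fluctuation around a baseline, clipped below the threshold by
  the precondition $\mu + 4\sigma < 5.5$; escaping traces jump above the
  threshold exactly at the requested crossing frame and are capped at the
  10 Å censor value, since a real early-stopped run terminates at the
  crossing. A literal shallow drift cannot guarantee a frame-exact
  crossing under noise, which is why the onset is steep. These are
  statistical stand-ins — no force field, membrane or solvent physics.
* **Screens** (`makeScreen`): Gaussian scores with actives planted either
  in the top bin (closed-form expected EF) or uniformly (EF = 1 in
  expectation); rows are shuffled so ranking order cannot leak from row
  order.

Passing tests on these fixtures therefore demonstrate correctness of the
statistics and bookkeeping under known ground truth — they cannot
demonstrate that any particular docking engine or force field would
reproduce the published screen.

## Numerical and degenerate-input choices

* Bond perception: atoms bond when their distance lies in
  $[0.4, r_i + r_j + 0.45]$ Å over single-bond covalent radii — used
  only when a format supplies no bond block.
* Altloc resolution keeps the highest-occupancy conformer, ties to `A`.
* Multi-molecule ligand files: first molecule, with a warning.
* Non-monotone time columns, empty structures, zero-atom records and
  unknown element symbols are hard errors naming the offending item.
* Replicate grids that differ are resampled by nearest time with a
  warning rather than silently interpolated.
* All tie-breaks (ranking, mapping order, benchmark labels) are
  lexicographic, making every report deterministic; the end-to-end
  pipeline is byte-identical under a fixed seed and config.

## Worked example

```{r}
# pose scoring on a fully planted pocket
fx <- makePocketFixture(nKeyContacts = 9, nHbonds = 4, nDecoys = 5, seed = 1)
report <- keyResidueScore(fx$ligand, fx$receptor)
report

# screen enrichment at the published configuration
scr <- makeScreen(877, 4, "top_bin", seed = 3)
enrichmentFactor(rankCompounds(scr$table), 0.01)

# stability statistic on the published window medians as constant series
ref <- mdReferenceMedians()
res <- lapply(seq_len(nrow(ref)), function(i) {
  reps <- lapply(1:3, function(r)
    RmsdSeries(0.1 * 1:100, rep(ref$median_rmsd[i], 100)))
  compoundStability(ref$name[i], reps)
})
head(rankLigands(res), 3)
```

## Problem sizes

The suites run at deliberately desk-scale sizes: the exhaustive mapping
oracle covers 100 random molecules of up to 8 heavy atoms (beyond which
factorial enumeration stops being an oracle and starts being a liability),
interaction closure uses 50 seeded pockets, stability recovery 50
replicate triples of 1000 frames, and the Monte-Carlo EF check 200 seeded
screens of 1000 compounds. These sizes give exact or tightly-bounded
expectations while keeping the full suite in the tens of seconds.

## Known limitations

* Isomorphism enumeration is exponential in highly symmetric molecules;
  the cap turns that into an explicit error.
* H-bond typing covers N/O donors/acceptors only — no sulfur, halogen
  bonds, π-stacking or salt bridges; those would gate on chemistry this
  package does not model.
* The enrichment module reports EF only; early-recognition metrics
  (ROC/AUC, BEDROC) are out of scope.
* mmCIF, PDBQT and binary trajectory formats are not read; series enter
  as precomputed tables.
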