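---
title: "Modelling disordered regions onto structural templates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disordered regions onto structural templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrbuilder)
```

## The problem

Intrinsically disordered regions (IDRs) populate heterogeneous
conformational ensembles rather than a single fold. In crystallographic and
cryo-EM structures they appear as missing coordinates; in machine-learning
predictions they are present but flagged by low per-residue confidence
(pLDDT). A single static placement of such a region is not meaningful — the
scientifically useful object is an ensemble of physically plausible
conformers attached to the folded template. `idrbuilder` generates such
backbone ensembles for three segment classes: N-terminal tails (N-IDRs),
linkers between folded elements (L-IDRs) and C-terminal tails (C-IDRs).

## The procedure and its assumptions

### Segment detection

Detection is positional: author residue numbering maps each observed
residue onto the full-length sequence, and any disagreement between the
observed residue type and the sequence letter is a hard error rather than a
trigger for alignment. This assumes the template is a literal sub-structure
of the supplied sequence, which holds for deposited structures paired with
their own constructs. A residue missing any of N, CA or C is treated as
wholly missing and rebuilt: a partial backbone cannot anchor a fragment or
contribute torsions. For predicted structures, `trimLowConfidence()`
deletes residues with pLDDT strictly below the threshold (default 70,
stored in the B-factor column as AlphaFold does) and classifies the deleted
runs exactly as detection would.

### The torsion library

Sampling is knowledge-based: (φ, ψ, ω) records are harvested from X-ray
chains at resolution ≤ 1.8 Å, in maximal runs broken at chain breaks
(peptide C–N above 1.6 Å) and at incomplete backbones. Two details matter:

* Run ends have undefined angles (the first residue has no φ, the last no
  ψ/ω). The sampleable fragment records are therefore the *interior*
  residues of each run — complete (φ, ψ, ω) triples — while junction
  geometry statistics use every defined junction including run ends. This
  keeps sampled paths free of undefined angles without discarding geometric
  information.
* Phosphorylated Ser/Thr (SEP/TPO) are indexed under their parent letters,
  so sampling for S or T reaches both the modified and unmodified record
  families; the record keeps its original residue name for provenance.

The ω summary uses circular statistics (trans peptides cluster at ±180°,
where an arithmetic mean is meaningless), and the gap-closure criteria take
their ω mean and spread from the trans pool only (|ω| > 90°).

### Backbone construction

Fragments are built sequentially from internal coordinates with fixed
covalent geometry (N–Cα 1.458, Cα–C 1.525, C–N 1.329 Å; N–Cα–C 111.0°,
Cα–C–N 116.2°, C–N–Cα 121.7°) and sampled torsions only. The carbonyl O is
placed in the peptide plane anti to the next amide nitrogen (ψ-based for
the terminal residue) and the amide H anti to the preceding carbonyl; no H
is built on proline. Holding bond geometry fixed is a deliberate
simplification — the variance that matters for disordered-state sampling
lives overwhelmingly in the torsions — and it is what makes the exactness
oracles below possible. Dihedrals follow the IUPAC sign convention
(verified in the tests against two independent formulations and an external
structure library).

### Attachment and clash screening

Each candidate fragment is built with one extra residue: a copy of the
template anchor on the anchored end. Superposing the copy's N/CA/C onto the
anchor's backbone (Kabsch: SVD of the covariance, with the reflection
branch corrected by the determinant sign) is an exact three-point fit for
ideal geometry, and fixes both the position and the junction geometry of
the fragment; the copy is then discarded. One-residue anchoring keeps the
attachment local — it does not distort the template and inherits the
junction ω directly from the sampled path.

A candidate is accepted only if no atom pair against the clash context
comes closer than r_i + r_j − tolerance, with a united element-keyed
radius table and a subtractive tolerance of 0.4 Å. The context contains
the template, all previously placed fragments, and any environment atoms
(e.g. a membrane slab) supplied for screening only. The anchor residues'
own atoms are excluded: they are covalently bonded to the built chain.
Intra-fragment self-clashes are not screened; the rejection step exists to
remove chains that collide with the fixed surroundings. The neighbour
search is a uniform cell list whose counts are asserted (in the tests and
the acceptance script) to equal the all-pairs brute force exactly.

### Gap closure

Internal gaps cannot be closed by forward building alone: the chain must
arrive at the downstream anchor with correct peptide geometry. The closure
search grows `poolSize` fragments from the upstream anchor and `poolSize`
from the downstream anchor (built forward as gap + anchor copy, then
anchored at the downstream side), each spanning the full gap, and scans
fragment pairs for a junction residue i where

* d(C_i, N_i+1) and d(C_i, Cα_i+1),
* the Cα_i–C_i–N_i+1 bond angle, and
* the ω torsion Cα_i–C_i–N_i+1–Cα_i+1 (compared on the circle, so −179°
  vs +179° is a 2° deviation)

all lie within mean ± `nSigma`·σ of the library's junction statistics
(tolerances floored at 10⁻³ so zero-variance ideal libraries still admit
exact matches). The accepted chimera — forward[first..i] +
backward[i+1..last] — has its junction carbonyl O and amide H remodelled
in the new peptide plane (no H for proline) and must then pass the clash
screen. A forward fragment whose last residue closes directly onto the
downstream template anchor is also accepted; that route is the only one
for a single-residue gap and the only one in `anchor_only` mode. Pairs are
scanned in pool order with the junction index ascending, and the first
passing candidate is taken: this is ensemble generation, not optimisation,
and first-hit acceptance keeps results reproducible. On failure the report
carries the best candidate's per-criterion deviations.

Two design points deserve emphasis:

* **Closure is a rare event.** A junction must hit a ~0.04 Å distance band
  and two angular bands simultaneously; the empirical per-pair pass
  probability on realistic fixtures is of order 10⁻⁶. Success therefore
  scales with `poolSize`² × (gap length), which is why the default pool is
  4000 per side and the ensemble driver retries a failed gap with fresh
  pools (`closureRetries`, default 4). This mirrors how the underlying
  approach operates in practice: full fragment ensembles from both sides,
  not a handful of candidates. The prefilter on d(C–N) makes the all-pairs
  scan affordable (the full four-criterion evaluation runs only on the
  distance-band survivors).
* **Sampled paths are ω-screened.** Every peptide ω that will become a
  junction of a built fragment is drawn from the library, and a draw
  outside the criteria band would re-emit a junction the closure check
  itself rejects. Such paths are redrawn at sampling time, so emitted
  conformers satisfy the junction screen at every built position by
  construction — terminal attachments included.

### Ensemble assembly

Per conformer, segments are processed chain by chain in template order and
longest-first within a chain (ties: N-terminal first); accepted fragments
join the clash context of later segments, which is what makes multi-chain
and multi-segment templates consistent. Conformer k uses seed
`seed + k`, so ensembles are reproducible end to end and individual
conformers can be regenerated in isolation.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `plddtThreshold` | 70 | pLDDT | strict cutoff for trimming predictions |
| `maxResolution` | 1.8 | Å | X-ray resolution cutoff for library chains |
| `chunkMax` | 5 | residues | longest library sub-run match per draw |
| `tolerance` | 0.4 | Å | subtractive van der Waals clash tolerance |
| `retryBudget` | 100 | draws | candidates per terminal segment per conformer |
| `poolSize` | 4000 | fragments | per-side pool for gap closure |
| `closureRetries` | 4 | calls | fresh-pool closure attempts per gap |
| `nSigma` | 3 | σ | width of the closure criteria bands |

The chunk-with-backoff sampler (`chunkMax` 5 → 1) is this package's own
declared scheme for sequence-conditional sampling; it preserves local
sequence/structure correlation up to 5-mers while guaranteeing that any
sequence with single-letter coverage can be built.

## What the synthetic fixtures emulate — and what they do not

All tests and the acceptance script run on fixtures built in code:
reference chains with canonical secondary-structure torsions (helix
−57/−47, strand −120/130, jittered coil), deletions with the original kept
for reconstruction oracles, lattice slabs standing in for bilayer atoms in
clash checks, and miniature torsion libraries. The library generator has a
`geometryNoise` switch: at 0 every source chain has exactly ideal covalent
geometry, which makes the zero-variance exactness oracles possible; at 1
bond lengths, angles and ω spread across chains with Engh–Huber-magnitude
standard deviations (0.014–0.021 Å, ~2°, 5.8° on ω), emulating the natural
geometric dispersion of a real high-resolution database — without it, the
closure criteria have floor-width bands and stochastic gap closure is
impossible, exactly as it would be with a single-structure "database".

One regime difference matters when running against a miniature library:
the chunk sampler takes the *longest* sub-run with at least one match, and
in a library of a few hundred records a given 2–5-mer often occurs exactly
once, which collapses path diversity (every drawn fragment is nearly the
same chain) and with it the stochastic closure search. Against a
full-size database every chunk length has many matches and the default
`chunkMax = 5` is the right setting; against the miniature fixtures the
stochastic-ensemble runs use `chunkMax = 1`, which gives the mini library
the per-position diversity a real one would have at longer chunks. The
chunked matching itself is exercised by the verbatim-retrieval and exact
reconstruction checks.

Passing on fixtures demonstrates the geometric and statistical contracts:
exact reconstruction, correct superposition, exact clash counting,
calibrated sampling, junction integrity, reproducibility. It does not
demonstrate that ensembles of real proteins reproduce experimental
observables — the fixtures are poly-alanine-dominated, have no side chains,
and their torsion libraries are far smaller than a PDB-derived one. Real
use requires building a library from actual high-resolution chains and,
where data exist, downstream reweighting.

## Numerical choices and degenerate inputs

* Dihedrals live in (−180°, 180°], with −180 mapped to +180; values within
  10⁻⁹ of the boundary are normalised on library deserialisation.
* Altloc resolution keeps the highest-occupancy copy, ties to the first
  encountered; model 1 of multi-model files is the default template.
* Segments of length 1 use the same machinery throughout (closure
  degenerates to junction checking against the downstream anchor).
* Collinear reference atoms make a dihedral undefined; the geometry
  primitives raise errors rather than returning NaN.
* A gap whose anchors are geometrically unreachable fails with a
  closure-failure report listing the best candidate's deviations; the
  ensemble driver converts persistent failure into a structured
  `idrSamplingFailure` condition carrying the segment and attempt count.
* Problem sizes in the tests and acceptance script (chains of 14–20
  residues, 2–6 conformers, pools of 4000) were chosen as the smallest
  sizes at which every contract — including stochastic gap closure — is
  exercised meaningfully.

## Known limitations

* Backbone only: no side-chain packing (the intended workflow packs side
  chains downstream) and no placement of phosphate atoms; phospho-residues
  influence sampling only through their torsion records.
* No experiment-biased sampling; the library is the only prior.
* Closure searches fragment pairs; it is not an analytic inverse-kinematics
  method, and very short gaps between rigidly fixed anchors can be
  genuinely hard (success scales with pool size).
* Sequence/structure matching is positional, not alignment-based.
* DSSP is not reimplemented: ensemble reports classify (φ, ψ) by fixed
  Ramachandran rectangles, a deliberate simplification for summary plots.
  Users wanting DSSP run it on the written PDB files.
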