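---
title: "Scaffold-constrained molecular graph generation with a Wasserstein GAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold-constrained molecular graph generation with a Wasserstein GAN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model, the
representation, the numerical choices, what the synthetic data emulate, and
where the edges of the method lie.

## The problem

De novo design around a privileged scaffold asks a generative model to
produce molecules that are chemically valid, novel, mutually distinct, and
that retain a fixed core — here the quinoline bicyclic. `molwgan` trains a
generative adversarial network directly on molecular graphs: no SMILES
grammar, no fragment library, just atoms, bonds and their one-hot tensors.

## Representation

A `graph_schema` fixes the encoding: an ordered element vocabulary, an atom
budget `N`, five bond classes (an explicit no-bond class, then single,
double, triple, aromatic), optional formal-charge classes and optional
tetrahedral-chirality classes (`none`, `cw`, `ccw`). A molecule becomes

* an adjacency tensor `A` of shape `N × N × B`, one-hot over bond classes,
  symmetric, with a no-bond diagonal, and
* a feature matrix `X` of shape `N × F`, with one-hot blocks for atom type
  (plus a pad class), charge and chirality.

Three encoding decisions deserve justification:

* **Hydrogens are nodes.** The element vocabulary includes H, so explicit
  hydrogens count toward `N`. This makes the graphs larger and the
  generation task harder (H atoms must learn to be univalent leaves), but
  it keeps the tensor a complete description of the molecule. Whether an
  atom budget "counts hydrogens" is therefore a property of the schema; the
  presets assume it does, and `max_atoms` is exposed for anyone who wants
  the heavy-atom convention.
* **Aromatic bonds are a bond class, not kekulized away.** Aromatic
  perception is re-done at decode time (see sanitization); encoding the
  delocalized form avoids teaching the generator an arbitrary kekulé
  assignment.
* **Tetrahedral parity only.** Chirality is encoded per atom as
  none/clockwise/anticlockwise relative to the neighbour list in atom-index
  order. Double-bond (E/Z) stereo is *not* encoded: the schema family this
  package targets adds "chiral centres and charges" to the graph, and
  extending one-hot node features to bond-anchored stereo would change the
  tensor contract. Stereo-aware canonical SMILES are used for
  novelty/uniqueness only when the schema encodes chirality, so the metric
  never distinguishes molecules the model itself cannot distinguish.

### Decoding and what "valid" means

Decoding enforces the structural invariants first (one-hot rows, symmetry,
no-bond diagonal, pad consistency); violations are *structural* errors and
are counted separately from chemical invalidity, because a generator that
emits malformed tensors has a software bug, not a chemistry problem.
Pad rows may appear anywhere — contiguity is an encoding convention, not a
decoding assumption.

Chemical sanitization then decides validity, in three steps: aromatic
bonds must lie in rings of the aromatic subsystem between aromatizable
elements with aromatic degree 2–3; a kekulé structure must exist (found by
backtracking over the atoms that need exactly one double bond, with
element/charge-dependent rules for which atoms those are); and every
atom's bond-order sum must not exceed an allowed valence for its element
and formal charge. Under-filled heavy atoms are completed with implicit
hydrogens and a bare H node is read as the [H] radical — both mirror what
the standard toolkits accept; only over-valence, impossible aromaticity
and unkekulizable systems are invalid. No Hückel electron counting is
applied: a kekulizable anti-aromatic ring passes, which is more permissive
than some toolkits and is a documented perception choice. `connected`
additionally requires a single component over non-pad atoms, and the
canonical SMILES always describes the whole decoded object (fragments
joined by `.`), never just the largest fragment.

Canonicalization itself is delegated to OpenBabel; the package's own
SMILES parser/writer handles the graph-level conversion (including
converting tetrahedral parity between writing order and index order) and
was validated by round-tripping every fixture molecule through
encode → decode → canonical SMILES.

## The networks

The generator maps a latent vector (`latent_dim`) through two dense layers
(`gen_units`) to initial node states and raw edge logits; the softened edge
distribution (symmetrized, diagonal-masked, per-pair softmax) then drives
`gcn_layers` rounds of relational graph convolution

    h'_i = act( W_self h_i + sum_b sum_j A[i,j,b] W_b h_j / max(1, d_{i,b}) )

refining the node states; a per-node head emits the feature blocks
(per-block softmax) and a bilinear head adds node-pair structure to the
edge logits before the final symmetrization and softmax. The critic embeds
the node features, runs the same relational convolution stack over the
(hard, soft or interpolated) adjacency, pools with a pad-weighted sum
readout (`weight_i = 1 − P(pad_i)`, which keeps the readout differentiable
for the gradient penalty's interpolated inputs and makes the score exactly
permutation invariant), and finishes with a two-layer dense stack
(`disc_units`, dropout) and a linear scalar output — a Wasserstein critic,
no sigmoid.

Losses are the usual WGAN-GP pair; the penalty interpolates real and fake
*jointly* on adjacency and features with one `ε ~ U(0,1)` per pair, and the
gradient norm runs over all coordinates of one sample. Because the penalty
differentiates the critic's input gradient, its parameter gradient is a
second derivative; the bundled reverse-mode engine builds its backward
passes out of its own primitives, so differentiating a gradient is exact
(verified against numerical differentiation, and against the closed forms:
a linear critic with unit-norm weights gives penalty 0, norm 3 gives 4, a
constant critic gives 1).

During training the critic is evaluated once per minibatch on a
block-diagonal stacking of the samples; block structure keeps samples
independent, so batched scores and per-sample input-gradient norms (masked
to each block) equal the per-sample computation — it is purely a
performance device.

### Hyperparameters

`make_config()` ships four named presets (base / model1 / model2 / model3)
covering the tuned combinations of latent dimension (64–256), activation
pairing (Tanh/ReLU or LeakyReLU), optimizer (Adam 1e-5 or RMSprop
1e-5/1e-4), dropout (0.01–0.5), generator/discriminator width (512 or
4092) and batch size (32/128, with 512 recorded as an alternative for the
largest model). Where a source prints both 4092 and 4096 for the large
width, the tabulated 4092 is used. Knobs the presets leave open take
package defaults: `gcn_units = 128` (the tabulated "neuron units" row),
`gcn_layers = 3` ("several" refinement rounds), `gp_lambda = 10` and
`n_critic = 5` (both WGAN-GP conventions). `activation = "tanh_relu"`
assigns tanh to the dense stacks and ReLU to the GCN layers; the pairing
is configurable because the two names arrive as a pair without an
assignment. Adam runs with β = (0.5, 0.9) (the GAN convention) and RMSprop
with decay 0.9 and no momentum. Weights are uniform-Glorot, seeded from
`config$seed`.

One initialization choice matters in practice: output-head biases start at
log marginal class frequencies (bonds overwhelmingly absent, then single;
C/H-dominated atom types; neutral charge; no chiral tag), and the bilinear
edge head starts at zero so those priors are not swamped by noise. An
untrained generator then emits sparse, single-bond-dominated graphs —
around the 5–7% bond density real molecular graphs have at this size —
instead of uniformly dense garbage. The aromatic class is deliberately
rare at initialization even though aromatic bonds are common in quinoline
data: isolated aromatic bonds sampled independently of ring context are
never valid, so the prior favours what independent sampling can get right
and training grows the ring systems.

### Discretization

`discretize()` turns the generator's distributions into a one-hot graph:
`argmax` (deterministic), `categorical` (seeded; implemented by the
Gumbel-argmax construction, which samples the same distribution), or
`gumbel_st` — the straight-through estimator used on the training path
(hard samples forward, gradients to the soft distribution backward). All
modes decide the upper triangle and mirror it, force the diagonal to
no-bond and restore pad consistency, so every discretized graph satisfies
the tensor invariants by construction.

## Training loop and stopping

One *iteration* = one generator update plus its `n_critic` critic updates
(the terms iteration and epoch are used interchangeably in parts of this
literature; this package always means generator updates). Every
`eval_every` iterations a snapshot of `eval_samples` graphs (default 100)
is sampled on a dedicated PRNG stream — evaluation cadence therefore never
perturbs the training trajectory — decoded, and scored. Two early-stopping
rules watch the history: *connectivity collapse* (connected validity zero
for `collapse_patience` consecutive snapshots after once being positive)
and *plateau* (best connected validity unimproved by more than `min_delta`
for `plateau_patience` snapshots). Defaults are 10, 0.01 and 50; a flat
history satisfies the plateau rule by construction, so short exploratory
runs that start at zero should raise `plateau_patience`. The best
checkpoint is tracked lexicographically by (connected validity, validity),
so a run that never achieves connectivity still keeps its most
chemically-productive parameters; the last checkpoint is kept alongside.
Non-finite losses abort with a diagnostic state dump rather than training
through NaNs.

All randomness fans out from one master seed into named streams (fixtures,
init, training, evaluation, generation, discretization), which is what
makes loss traces bit-reproducible and lets any stage be re-run
independently.

## Metrics and exhaustive generation

The metric denominators are deliberate and differ:
validity is over all generated graphs; connected validity over valid
molecules; scaffold rate over connected valid molecules; novelty and
uniqueness over valid molecules. Connected validity above validity is
therefore perfectly coherent (a batch can decode 25% valid of which 64%
connected). `exhaustive_generate()` repeats runs of `run_size` graphs and
archives connected, valid, scaffold-containing molecules that are novel
against the reference and not yet archived, stopping after `patience`
consecutive runs that add nothing (both default 100). Archive admission is
stricter than the novelty metric on purpose: the archive is the
deliverable set, the metric is a rate over valid molecules.

Scaffold matching is substructure *containment* of the quinoline query,
not Murcko-scaffold equality — further-fused systems containing the core
count as scaffold hits, consistent with reading "share of quinoline
molecules" as retention of the pharmacophore rather than exact-core
identity. The choice is exposed via `scaffold_query`.

## Synthetic data: what it does and does not emulate

`enumerate_quinolines()` decorates the quinoline core at its aromatic CH
positions with a small substituent panel (methyl, hydroxyl, amino, fluoro,
chloro, methoxy, thiomethyl, carboxamide, N-methylamino, and a chiral
sec-butyl so chirality columns are exercised), up to `max_substitutions`
sites, in a seeded random order, de-duplicated by canonical SMILES and
filtered against the schema. This reproduces the *structure* of a
scaffold-constrained training set — shared core, peripheral variation,
charge/stereo diversity under the full schema — which is what the
pipeline's correctness properties need. It does **not** reproduce the
property distributions of real vendor libraries (molecular weight and
logP ranges, ring-system diversity, substituent frequencies), so green
tests here say the machinery is right, not that the model has seen
realistic chemistry.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a single CPU: round-trip
fidelity uses 200 molecules per schema preset; the metric oracle runs
1,000 random batches; symmetry contracts use 100 random graphs and 1,000
latent draws; the smoke training run uses 500 fixtures capped at 25 atoms,
a latent dimension of 8, 32 dense units, 16 GCN units, 2 GCN layers, batch
size 4 and 500 iterations with 12-sample snapshots; the acceptance script
trains 300 iterations and evaluates 100-graph snapshots, with exhaustive
generation at `run_size = 50`, `patience = 20`. These are the package's
chosen demonstration sizes; the same code paths scale to the full presets
on better hardware. At these sizes a useful mental model is: the GAN
reliably learns sparsity and bond-class statistics (losses fall, validity
becomes intermittently positive), while full connectivity of 20-atom
quinolines is a longer-horizon objective — the headline rates reported by
GPU-scale runs of this architecture (validity ~0.25, connected validity
~0.62, >90% scaffold/novelty/uniqueness) are not reachable in minutes of
CPU time, and nothing in this package pretends otherwise.

Numerical details worth knowing: softmaxes are max-shifted (exact for the
distribution, exact for the gradient); the per-pair edge softmax assigns
the diagonal no-bond probability exactly 1 by construction rather than by
±large logit masking; degree normalization clamps at 1 to avoid dividing
by vanishing soft degrees; categorical sampling uses Gumbel-argmax with
probabilities floored at 1e-12 inside the log; ties in discretization
resolve to the first class (deterministic); the t-SNE embedding is the
exact quadratic algorithm with bisection-calibrated perplexity, early
exaggeration and momentum, suitable for the few-thousand-point sets used
here.

## Drug-likeness screen

`lipinski()` computes MW and an atom-contribution logP via OpenBabel, and
counts donors (N/O bearing hydrogen) and acceptors (all N + O — the
original rule-of-5 convention, stated explicitly because acceptor
definitions vary). The rule is `hbd ≤ 5`, `hba ≤ 10` (inclusive), `mw <
500`, `logp < 5` (strict), and every record carries its own descriptors so
the verdict is recomputable. `sa_score()` implements the Ertl
synthetic-accessibility score: a count-weighted fragment-contribution term
over circular environments of radius 0–2 (with the count-fingerprint
deduplication rule: an environment whose bond set has appeared before is
not re-counted), complexity penalties (size, stereocentres, spiro and
bridgehead atoms from the smallest-set-of-smallest-rings, macrocycles) and
a symmetry correction, mapped to the 1–10 scale with logarithmic smoothing
of the top end. The shipped fragment-score table covers the
quinoline-focused chemical space this package works in; environments
outside it take the rare-fragment default (−4), so scores for exotic
chemistry should be read as rough. Agreement with the reference
implementation is within 1e-3 across the 50-molecule benchmark panel.

Toxicity is an interface, not a model: `screen()` accepts any function
returning a 12-column matrix of activity probabilities over the Tox21
panel (NR-AR … SR-p53), applies the 0.5 inactivity threshold, and can rank
by mean predicted activity. Training an actual Tox21 predictor requires
the external assay data and is out of scope; a deterministic synthetic
stub ships for tests and examples and has no toxicological meaning.

## Known limitations

* OpenBabel is the canonicalization authority; its canonical SMILES are
  deterministic but not interchangeable with other toolkits' canonical
  forms, so novelty comparisons must use this package's `canonicalize()`.
* E/Z stereo is neither encoded nor generated, and is stripped before
  stereo-aware comparisons of decoded molecules.
* Sanitization accepts radicals and skips Hückel counting (documented
  above); validity is therefore marginally more permissive than RDKit's.
* The exact t-SNE is quadratic in points; subsample references above a few
  thousand molecules.
* Training at the full preset sizes (4092-unit networks, million-molecule
  libraries) is out of reach of the pure-R engine; the presets are
  faithful records and small-scale-runnable, not CPU-practical at full
  size.
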