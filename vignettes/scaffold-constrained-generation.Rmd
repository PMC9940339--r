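---
title: "Scaffold-constrained molecule generation: models and methods"
author: "scafgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold-constrained molecule generation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Medicinal chemistry rarely starts from nothing.  A project usually owns a
handful of privileged fragments — a furan, a triazine, a xanthine core —
and asks for complete, drug-like, *active* molecules that contain them.
`scafgen` addresses exactly this setting: the user supplies a *scaffold*,
a combination of one or more fragments (possibly disconnected), and a
generator grows and links those fragments into full molecules, optimized
against multiple objectives by reinforcement learning.

The package implements the whole pipeline: BRICS fragmentation of a
training corpus into scaffold–molecule pairs, two molecular
representations (SMILES token sequences and a five-row graph matrix),
four encoder–decoder generator architectures, Pareto-ranked
policy-gradient reinforcement learning, and population-level evaluation.

## Data construction

Each training molecule is decomposed with the BRICS rules into its *leaf*
fragments — pieces that no rule can cleave further.  If more than four
leaves exist, only the four largest by heavy-atom count are kept (ties
broken by canonical SMILES).  Every non-empty subset of the retained
fragments becomes one input scaffold, joined with `'.'`, and is paired
with the full molecule: a molecule with $n$ leaves yields $2^n - 1$
pairs.  Fragment order inside a scaffold is randomized so the model never
learns an order convention.  Pairs are split 8:1:1 into
train/validation/test **by scaffold** (the scaffold identity is the
sorted fragment multiset), so no scaffold leaks across partitions;
validation and test each receive $\lceil N/10 \rceil$ scaffolds.

Activity labels are pChEMBL values ($pX = -\log_{10}$ molar potency);
duplicate structures are collapsed to their mean $pX$, and a molecule is
called *active* when $pX \ge 6.5$ (about 316 nM).  Standardization keeps
the largest organic component, neutralizes charges where chemically
possible (quaternary nitrogens stay charged, with a log flag), rejects
structures whose largest component holds an element outside
B/C/N/O/F/Si/P/S/Cl/Se/Br/I, and canonicalizes.  Stereochemistry is kept
as given and tautomers are not canonicalized — the preprocessing rules
say nothing about either, so we prefer the least destructive reading.

## The graph representation

The distinctive representation is a $5 \times L$ integer matrix whose
rows are (atom type, bond type, connected atom index, current atom index,
fragment index) and whose columns fall into three sections:

    [GO] [fragment columns] [growing columns] [EOS] [linking columns] [EOS]

Molecules are **kekulized** before encoding, because aromatic bond orders
have no well-defined contribution to an atom's valence sum; aromaticity
is re-perceived by sanitization on decoding.  The first occurrence of an
atom carries its element token and the bond to an already-placed atom
(an empty `*` bond when it opens a fragment); a column that re-references
two placed atoms (ring closure) carries an empty atom type.  Linking
columns join fragment-derived components with single bonds only — BRICS
cleaves single bonds, so this loses no generality on BRICS-derived data.

The vocabulary holds 38 atom-type tokens (the organic subset with
explicit charge states) and exactly four bond types (none, single,
double, triple).  Two index formulas turn a column into transformer
inputs: the word index $W = T_{atom} \times 4 + T_{bond}$ (injective
because there are exactly four bond types) selects a learned embedding,
and the position index $P = I_{atom} \times L_{max} + I_{connected}$
feeds the sinusoidal positional encoding
$PE_{(p,2i)} = \sin(p/10000^{2i/d_m})$,
$PE_{(p,2i+1)} = \cos(p/10000^{2i/d_m})$.

Atom traversal inside a fragment is breadth-first from the atom of lowest
canonical rank, neighbors visited by canonical rank.  Any deterministic
order works; canonical ranking makes encode–decode round-trips exactly
reproducible, which the test suite checks across the whole fixture
library and every fragment subset.

## Valence masking

During graph generation the package tracks, for every placed atom, its
remaining valence (maximum minus the running bond-order sum), the
connected components, and the section phase.  At each of the four
decisions per column, only continuations that keep every atom within its
maximum valence — and the matrix structurally well-formed — are
permitted; the end token is always permitted, so the mask is never
empty.  Maximum valences are per element/charge (C 4, N 3, N+ 4, O 2,
O− 1, S ≤ 6, P ≤ 5, halogens 1, B 3, ...), chosen to coincide with what
sanitization accepts, so *every* sampled matrix decodes to a valid
molecule.  This is a structural guarantee, not a statistical one: the
test suite samples 10,000 matrices under a uniform *random* policy — the
most adversarial policy the mask admits — and requires zero decode
failures.

Sequence models get no such mask (only vocabulary masking); their
invalidity rate is a property of interest, not a bug, and is measured by
the validity coefficient.

## The four generators

* **Graph transformer** — transformer encoder over the fragment columns;
  causal transformer decoder over the generated columns; a GRU head
  decodes the four decisions of each column one by one (atom type, bond
  type, connected index, current index), each conditioned on the previous
  decisions through the recurrent state.  The loss is the sum of the four
  per-decision negative log-likelihoods.
* **Sequence transformer** — token-level encoder–decoder with sinusoidal
  positional encodings, multi-head scaled dot-product attention
  ($\mathrm{softmax}(QK^\top/\sqrt{d_k})V$), residual connections and
  layer normalization.
* **LSTM-BASE** — embedding (128) + three LSTM layers (512); the
  encoder's final hidden/cell states initialize the decoder.
* **LSTM+ATTN** — LSTM-BASE plus dot-product attention over encoder
  outputs; the context vector is concatenated with the decoder embedding
  at every step.

Training minimizes teacher-forced NLL with Adam (learning rate $10^{-4}$,
batch 256 by default), selects the epoch with minimum validation loss,
and stops early after 100 non-improving epochs.  The networks run on a
small reverse-mode automatic-differentiation engine written in R (matrix
tape over BLAS primitives with a fused multi-head-attention node);
gradients are verified against finite differences in the test suite.
Transformer depth defaults to 3 encoder + 3 decoder layers with
feed-forward width $4 d_m$ — the paper-scale attention geometry
($h = 8$, $d_k = d_v = 64$, $d_m = 512$) is the default, and every test
uses a reduced desk-scale configuration ($d_m = 64$, 2 layers, 4 heads)
so the suite trains in minutes on one CPU.  Additional numerical
choices: gradient clipping at global norm 5, sampling temperature fixed
at 1 (pure multinomial), teacher forcing throughout supervised training.

## Multi-objective reinforcement learning

Two objectives are scored per molecule: QED drug-likeness (0–1) and
predicted affinity from a random-forest regressor (500 trees) on
2048-bit ECFP6 fingerprints plus 19 physicochemical descriptors.  The SA
synthesizability score is reported alongside but never optimized.  A
molecule is *desired* when its predicted $pX \ge 6.5$; a QED cutoff can
be added but is off by default — desirability follows the affinity score
alone, with QED shaping the Pareto ranking instead.

Solutions are ranked by non-dominated sorting ($m_1$ dominates $m_2$ iff
it is no worse in every objective and strictly better in at least one).
Within a frontier, molecules are ordered by their mean Tanimoto distance
to the other members — *smallest first*, so crowded molecules take the
low ranks and diversity is rewarded.  With the global 1-based rank $k$
assigning all undesired molecules below all desired ones,

$$R^* = \begin{cases}
  0.5 + \dfrac{k - N_{undesired}}{2 N_{desired}} & \text{desired} \\[1ex]
  \dfrac{k}{2 N_{undesired}} & \text{undesired}
\end{cases}$$

places undesired rewards exactly in $(0, 0.5]$ and desired rewards in
$(0.5, 1]$.  This interval structure is the package's acceptance target:
it is re-derived over hundreds of random populations rather than assumed.
Invalid generations (possible for sequence models) are treated as
undesired and ranked below every valid undesired molecule.

The policy gradient ascends
$J(\theta) = \sum_t \log G(y_t \mid y_{1:t-1}) \cdot R^*(y_{1:T})$,
with all four per-step decisions contributing for the graph model.  Two
details matter for this estimator to be well-posed under valence
masking: the log-probabilities are evaluated under the *same* masks the
sampler applied (otherwise the gradient spends capacity on continuations
that were never sampleable), and decisions that were forced — a
single-option mask, a structurally determined index — contribute zero
weight, since no choice was made there.  Each epoch an *exploring rate*
$\varepsilon \in [0,1]$ routes that fraction of scaffold inputs through
a frozen exploration net $G_\varphi$ (a general-corpus generator); all
generated molecules are scored and rewarded, only the exploitation net
$G_\theta$ is updated, and $G_\varphi$ is verified bit-identical before
and after.  Scaffolds are drawn with replacement from the training
pool, batch 64 by default.

At desk scale the RL learning rate is $3 \times 10^{-4}$: the supervised
rate ($10^{-4}$) barely changes the sampled trajectories within a
30-epoch horizon, while $10^{-3}$ drives desirability up quickly and
then destabilizes it — the same over-optimization the affinity-only
objective is known for (molecules ballooning in size to inflate the
predicted activity; the QED objective in the Pareto ranking counteracts
this).  Sampling itself runs through an incremental decoder with cached
attention keys/values, verified against the training-path forward.

## The synthetic fixture library

Full-scale corpora (ChEMBL-sized pretraining sets, receptor bioactivity
extracts) are deliberately out of scope; a synthetic library stands in
for them so every stage is testable end-to-end.  The generator decorates
five heteroaromatic core families — furan, triazine, aminotriazole,
xanthine-like and azapurine-like, the classic adenosine-receptor
antagonist chemotypes — with 15 small substituents at two slots,
yielding 924 distinct standardized molecules.  Each carries a
deterministic pseudo-activity: a family base value (4.8, 5.6, 6.9, 7.8,
8.3 on the $pX$ scale), a small term for decoration size
($0.04 \times$ substituent heavy atoms), and Gaussian noise with
$\sigma = 0.3$, clamped to $[3, 12]$.  Two families sit below and three
above the 6.5 activity threshold, so the library plants a
structure–activity signal that a fingerprint regressor recovers and
reinforcement learning can exploit.

What the fixtures do **not** emulate: the size and chemical breadth of
real corpora, activity cliffs, assay noise structure, stereochemistry,
tautomerism, and realistic scaffold overlap between train and test
chemistry.  A passing suite therefore demonstrates that the machinery is
correct and learns at desk scale — not that any particular accuracy or
novelty level transfers to real screening data.

## Problem sizes used by the tests

The suite trains the desk-scale graph transformer ($d_m = 64$, 2 layers,
learning rate $10^{-3}$, batch 64) for 30 epochs on a 300-molecule
fixture library (fragment subsets capped at size 2, ~750 pairs), then
samples 50 scaffolds 20 times each (1,000 molecules) for the validity
check; reinforcement learning runs 30 epochs × 5 seeds at batch 12 from
that same pretrained snapshot.  Oracle equivalences run over 200 random
populations (non-dominated sorting), matrices up to $m = 50$
(Solow–Polasky), the full 300-molecule library × all fragment subsets
(codec round-trip), and 10,000 random-policy matrices (mask fuzz).

## Evaluation

Five coefficients are computed over a generated population: validity
(parsable fraction), accuracy (fraction containing all scaffold
fragments — on the aromatic-perceived form, so the kekulization mismatch
documented under *Valence masking* is reported, not hidden), desirability
(desired fraction), uniqueness (distinct canonical structures /
$N_{total}$) and novelty (distinct structures absent from the reference
corpus / $N_{total}$; novelty ≤ uniqueness by construction).

Diversity uses the Solow–Polasky measure
$I(A) = \frac{1}{|A|}\, e^\top F^{-1} e$ with
$F = [e^{-\theta d_{ij}}]$, $\theta = 0.5$, over pairwise Tanimoto
distances on ECFP6 fingerprints.  Exact duplicates make $F$ singular and
are collapsed first; the $1/|A|$ normalization maps a single molecule to
1, so values live in $(0, 1]$ (an effective-number-of-distinct-members
per molecule).  The linear system is solved directly rather than by
explicit inversion; both routes agree to $10^{-8}$ in the tests.

## Known limitations

* The paper-scale benchmark numbers (validity/novelty tables from
  ChEMBL-pretrained models, absolute desirability and diversity of the
  full RL runs) require corpora and compute deliberately out of scope
  here; the package reproduces the *mechanisms* and their invariants at
  desk scale.
* Sequence-model encoders process padded positions; at corpus scale a
  packed-sequence implementation would train faster.
* The valence table is intentionally conservative for exotic charge
  states (e.g. halide anions get valence 0 and are never grown), which
  slightly narrows the theoretically reachable chemistry.
* Scaffold containment inherits substructure-matching semantics from the
  toolkit: a scaffold that aromatized while being grown counts as a
  miss, depressing the accuracy coefficient exactly as documented.
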