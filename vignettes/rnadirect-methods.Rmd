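---
title: "Template-reweighted coupling analysis for RNA tertiary contacts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-reweighted coupling analysis for RNA tertiary contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the two models it
combines, what every tunable parameter means, what the synthetic generator
does and does not emulate, and the numerical and design decisions that were
genuinely open.

## 1. Two signals, one score

Tertiary contacts — pairs of nucleotides more than four positions apart in
sequence whose heavy atoms approach within 8 Å — determine an RNA's global
fold, but they are the weakest part of what coevolutionary analysis can see
in an alignment. The package combines:

* a **coevolutionary signal**: mean-field direct coupling analysis (DCA) of
  the family alignment, summarised per pair as direct information (DI); and
* a **structural prior**: a contact-frequency template over position pairs,
  learned by a restricted Boltzmann machine (RBM) from contact maps of
  related structures, expressing how often each pair region is in contact
  across the structural class.

The final score is `DIRECT = DI × W²`, ranked over pairs with `|i − j| > 4`.

## 2. The contact definition

Two residues are in contact when the *minimum* distance over pairs of heavy
atoms, one from each residue, is strictly below the cutoff (default 8 Å; a
pair at exactly 8 Å is a non-contact — the strict inequality is applied
consistently in map construction, template thresholding and evaluation).
Hydrogens and waters are excluded at parse time; modified nucleotides are
kept whenever they carry at least one heavy atom, because the definition
needs coordinates, not base identity.

The sequence-separation filter (`> 4` nt) is applied at *prediction and
evaluation* time only. Training maps for the template machine keep the
near-diagonal pairs (`min_separation = 0`): the template should represent
the full contact pattern of the class, while the filter encodes what counts
as a tertiary prediction.

Missing residues in crystal structures are a silent hazard: maps are built
over the observed residues only, sequentially re-indexed, which keeps the
machine's input dense at the cost of a small register shift around gaps.

## 3. Template learning

### 3.1 Resizing

Structures of different lengths are brought to a common `M × M` grid
(default 100) by bilinear interpolation of the *distance* matrix — not of
the binary map — with the cutoff applied afterwards. The index convention
maps source index `i ∈ [1, L]` to target coordinate `i·M/L`, so a target
pixel `t` samples the source at `t·L/M` with edges clamped; sequence
separations scale with `M/L` (for `L = 50, M = 100`, a feature between
nucleotides 1 and 4 lands between target positions 2 and 8). No single
linear map can instead hold position 1 fixed while doubling position 4;
the proportional convention was chosen because it preserves separation
ratios, which is what the range classification depends on. Interpolation
treats the zero diagonal like any other entry; the near-diagonal band it
contaminates is removed later by the separation filter. Symmetry is
restored by averaging with the transpose.

### 3.2 The machine

The lower triangle of an `M × M` map, read row-major, feeds `M(M−1)/2`
binary visible units (4950 at `M = 100`). The RBM is binary-binary with
energy `E(v, h) = −bᵀv − cᵀh − vᵀWh`; the bipartite restriction factorises
both conditionals into logistics, which is what makes block Gibbs updates
and contrastive divergence (CD) cheap.

Training defaults: learning rate 0.1, 10 000 epochs, CD-1, full batch.
Choices the protocol leaves open, fixed here as package defaults:

| parameter | default | why |
|---|---|---|
| CD order `k` | 1 | standard and cheapest; exposed as `cd_k` |
| batch scheme | full batch | training sets are tens of maps; exposed as `batch_size` |
| initialisation | weights ~ N(0, 0.01²), biases 0, seeded | conventional small-scale start |
| negative phase | binary sampled states; positive phase uses data and hidden *probabilities* | standard CD practice, documented for reproducibility |
| Gibbs protocol | 10 000 sweeps, keep the last 5 000 | the protocol's stated sampling plan; both counts are config knobs |

The template weight is the per-pixel mean of the kept samples, unflattened
to a symmetric matrix in `[0, 1]` with the diagonal fixed at 0
(self-contacts are undefined). Regularisation (L1/L2) is deliberately not
implemented; at these training-set sizes the weights stay moderate.

### 3.3 Validation strategy

On machines small enough to enumerate (≤ 24 units) the package carries
exact oracles: the partition function, the visible distribution, the
likelihood gradient and the conditionals. The test suite uses them to check
normalisation, the logistic conditionals, stationarity of the Gibbs kernel,
and the CD-1 estimator. Two caveats worth stating honestly:

* CD-1 is a *biased* estimator of the likelihood gradient; the bias grows
  with coupling strength. The Monte-Carlo comparison against the exact
  gradient is therefore run at initialisation-scale couplings, where the
  one-step chain is near equilibrium and the bias sits below Monte-Carlo
  resolution. This validates the implementation, not the (well-known)
  estimator bias at strong coupling.
* A single Gibbs chain mixes slowly between well-separated modes of a
  sharply trained machine. Sampling fidelity is therefore checked on small
  bimodal machines with adjacent modes, where mixing is fast and the
  total-variation comparison against the enumerated distribution is
  meaningful.

## 4. Coupling analysis

The alphabet is `{A, C, G, U, -}` (`q = 5`), with the gap as an ordinary
state and as the gauge state dropped when the correlation matrix is built.
Rows (never columns) with gap fraction strictly above 50% are removed.
Redundancy is corrected by neighbourhood weights at 80% identity;
frequencies are pseudocounted with λ = 0.5 toward uniform (`λ/q` singles,
`λ/q²` pairs, self-pairs kept diagonal-consistent), so pair marginals equal
the singles exactly by construction. λ and the identity threshold follow
the conventions of the mean-field DCA literature and are exposed as
arguments.

Couplings are `e_ij = −(C⁻¹)_ij` over the `q − 1` non-gap states. The
two-site fields are fitted by alternating proportional updates (iterative
proportional fitting) until both marginal constraints hold within `tol`
(default 1e-6, cap 1000 iterations — in practice a few dozen suffice); DI
uses the natural logarithm, with `0 · log 0 = 0`. DI is computed for *all*
pairs; the separation mask is applied at ranking time, keeping the DI
matrix a pure function of the alignment.

## 5. Combining the two signals

The template lives on the `M × M` grid, DI on the target's `L × L` grid.
Predictions must be reported in target coordinates, so the template is
resized to `L × L` (same index convention, clipped to `[0, 1]`) rather than
mapping DI into template space. The exponent on `W` defaults to 2 and is
configurable 1–4: with entries in `[0, 1]`, higher powers suppress
uncertain template regions progressively; 2 balances the two signals.
Ranking breaks score ties deterministically by smaller `i`, then smaller
`j`.

## 6. What the synthetic generator emulates

`synth_contact_map()` lays nested hairpin stems (anti-diagonal bands, with
seeded placement jitter so different seeds give genuinely different
layouts) and 2 × 2 loop-loop patches between hairpins — the contact classes
the method targets. It also emits a pseudo-distance matrix (contacts in
[3, 8) Å, non-contacts in (8, 30] Å) so the full distance → resize →
threshold path is exercised; thresholding reproduces the map exactly by
construction.

`synth_family()` models a structural class as symmetric bit flips off the
stem bands (stems are preserved — real folded RNAs all keep their stems;
the default flip rate 0.1 makes the shared tertiary blocks the learnable
signal). `synth_msa()` plants pairwise couplings at a column-disjoint
subset of native contacts, sampling planted columns jointly from a 4 × 4
table with weight `exp(s)` on base-pairing states (A-U, G-C, G-U; default
`s = 3`, alignment depth 500, gap rate 0.05), other columns i.i.d. uniform.
Pairwise (not full-Potts) sampling is exact and sufficient to give DCA a
recoverable signal.

What it does *not* emulate: phylogenetic correlation between sequences,
non-uniform background composition, column-wise gap structure,
pseudoknotted stems, and any thermodynamic realism of the pseudo-distances.
Passing tests on this generator therefore demonstrate correctness of the
inference machinery and the claimed *direction* of the template effect
under ideal conditions — not performance on real families.

## 7. Problem sizes used by the tests

Enumeration oracles run at ≤ 12 visible + 4 hidden units. The end-to-end
synthetic study uses instances of length 70 (3 stems, 2 tertiary blocks,
20 family maps, flip rate 0.1, 500 sequences, coupling 3.0), with template
training shortened to 2 000 epochs and sampling to 2 000 sweeps keeping
1 000 — sizes chosen so the whole suite completes in minutes on one CPU
while leaving the learning signal intact. Because all family members of an
instance share one length, the template machine trains at that native size;
the resize path is exercised separately with its own fixtures. The
command-line defaults keep the full-scale protocol values.

## 8. Known limitations

* Pseudoknots are rejected, not modelled; the category classifier assumes
  nested stems.
* Homology between training structures and the target must be declared by
  the caller (`exclude_homologs()`); no sequence/structure search is
  performed.
* The mean-field inversion degrades on very shallow or highly redundant
  alignments; the pseudocount guards invertibility but cannot create
  signal.
* A mismatched template (structures unrelated to the target class) does not
  help and can mildly hurt ranking — the package's own control test checks
  that it at least does not fabricate gains.
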