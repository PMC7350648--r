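---
title: "Implied alignment on a binary tree: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implied alignment on a binary tree: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impliedalign)
```

## The problem

Given a rooted strictly binary tree whose `n` leaves carry unaligned
sequences of length at most `k`, and a pairwise alignment operator, the tree
*implies* a multiple sequence alignment: the bracketing of the tree fixes
the order in which pairwise alignments are composed. The operator is
required to be commutative but is deliberately not associative, so the
result depends on the tree topology (that is what makes the alignment
"implied" by the tree) but not on which child of a node is written first.
This construction is the alignment-side companion of direct optimization in
dynamic-homology phylogenetics, and is also usable as a stand-alone MSA tool
when a guide tree is available.

The package computes the implied alignment in two passes:

1. **Post-order** (`postorder_decorate()`): every internal node receives a
   *preliminary context* — the tagged alignment of its children's contexts —
   and a cost equal to the children's costs plus the local alignment cost.
   After the pass the root context summarizes the whole leaf set and the
   root cost is the tree cost.
2. **Pre-order** (`preorder_finalize()`): the root's final alignment is its
   own context; every other node's final alignment is derived from its
   parent by a *sliding zip* that threads gaps downward. All final
   alignments share one length `a`, and a leaf's final alignment, rendered
   to symbols, is its row of the MSA.

The zip makes the pre-order pass linear in the alignment length per node:
with `m = a/k` the pass runs in `Θ(k·m·n)`, between `Ω(k·n)` when every
sequence fits the longest one (`m = 1`, a "perfect" alignment) and
`O(k·n²)` when nothing aligns with anything (`m = n`, a "degenerate"
alignment). The post-order pass is bounded by the pairwise aligner, here a
full dynamic-programming matrix, `Θ(L²)` per node for context length `L`.

## The tagged alphabet and the alignment operator

Sequences are lifted from plain symbols to a tagged alphabet. A position of
an aligned context is one of

* `BOTH(x, y)` — the position aligned residues of both subtrees; `x` and
  `y` are the effective sets of the two consumed elements,
* `LEFT(x)` / `RIGHT(y)` — the position consumed a residue of only the
  first/second operand (an indel),
* `GAPPED` — the position originated in neither subtree; such elements are
  created only during the pre-order pass.

The four tags fit in two bits (`tag_encode()`); for an alphabet of `x`
symbols there are `(2^x−1)²` BOTH values, `2(2^x−1)` one-sided values and
one GAPPED value, `2^(2x)` in total. Symbol sets are bitsets under the
declared alphabet order, which also defines all lexical comparisons.

`align_tagged()` is a Needleman–Wunsch dynamic program over *effective
sets* with a traceback that records, for every output element, which
operand(s) it consumed. Costs come from a user-supplied symmetric,
nonnegative transition cost matrix with zero diagonal (`load_tcm()`),
expanded to nonempty symbol subsets: the cost of two sets is the minimum
pairwise symbol cost, and the median of two sets is every symbol minimizing
the summed distance through an intermediate symbol (Sankoff-style). For the
bundled matrices this median reduces to intersection-if-nonempty-else-union.
A triangle-inequality violation in the matrix is reported as a warning
only, because the algorithm needs symmetry and nonnegativity, not
metricity.

Commutativity is enforced by a deterministic operand assignment
(`canonicalize_pair()`): the longer operand fills the matrix columns; on
equal lengths the lexically first operand (elementwise comparison of
effective-set bitsets, ties to the shorter) fills the columns; if the first
argument was not assigned to the rows, LEFT/RIGHT tags are exchanged after
the traceback, so LEFT always means "came from the first argument".

### Effective sets: the indel-median convention

The operator consumes tagged strings but the cost matrix is defined on
plain symbol sets, so every tagged element must project to an *effective
set*. `BOTH(x, y)` projects to the median of `x` and `y`, and `GAPPED` to
the gap singleton. For indel-derived elements the package follows the
direct-optimization median convention and **includes the gap symbol**:
`LEFT(x)` projects to `x ∪ {gap}`. This is a genuine design decision with
visible consequences, and the reason the package exposes the alternative
(`load_tcm(..., gap_in_indel = FALSE)`, which projects `LEFT(x)` to
`x \ {gap}`):

* Under the DO convention, two indel-derived elements can re-align at zero
  cost against each other or against a new gap. On indel-preferring cost
  matrices this is what keeps mutually unalignable subtrees unalignable at
  *every* tree level: each join of the degenerate benchmark data remains
  fully staggered, the root context length grows as `a = n·k`, and the
  worst-case ratio `m = n` is reached exactly for every tree size — which
  in turn is what makes the pre-order pass exhibit its quadratic worst
  case. The gap-exclusive variant instead re-aligns the (identical)
  subtree contexts at zero substitution cost at the first join above the
  quartets, freezing `a` at `4k`; the worst-case regime then cannot be
  reproduced beyond four leaves. The two variants also price indels of
  indel-derived elements differently (this shifts the degenerate quartet's
  tree cost, as the unit tests record), but both reach `a = 4k` on a
  single quartet.
* On substitution-preferring matrices the two conventions agree on all the
  bundled examples: matches are strictly cheaper than indels, so the gap
  member of an effective set never wins.

For the same reason, co-optimal traceback steps resolve by the fixed
preference **leftward > upward > diagonal** (indel before match), applied
at matrix-fill time. Any fixed preference yields determinism and
commutativity; preferring indels is what lets zero-cost ties on
indel-preferring matrices keep degenerate data degenerate. Identical inputs
are detected during canonicalization but still go through the dynamic
program: on substitution-preferring matrices the all-BOTH zero-cost
alignment emerges by itself, while shortcutting would silently destroy the
worst-case regime above.

## The sliding zip

The zip derives a child's final alignment from three strings — the parent's
final alignment (the basis), the parent's context and the child's context —
consuming one parent-final element and emitting one output element per
step. Six cases are evaluated strictly in order (first match wins): gaps
propagate (Case 0); an exhausted child context yields gaps (Case 1); a
BOTH parent position passes the child's element through (Case 2); a
LEFT/RIGHT parent position passes the child's element through only on the
matching side (Cases 3–4); otherwise a new gap is emitted (Case 5).

Two details are underdetermined by the case prose and fixed here:

* **Case 1 consumption.** When the child's context is exhausted, the zip
  still consumes one parent-context element per step (the parent-final
  element is never GAPPED in this branch, since Case 0 precedes). This
  mirrors Case 5 and guarantees both contexts are exactly exhausted when
  the zip returns — enforced as a runtime check.
* **Case 0 consumption.** A GAPPED parent-final element consumes no
  parent-context element: contexts contain no GAPPED elements, so there is
  nothing to consume.

Element equality in Cases 3–4 compares tag and payload. Both traversals are
iterative (explicit orderings computed once per tree), so deep caterpillar
trees cannot overflow the call stack. The zip and the whole pre-order
traversal are compiled; the timing harness (`run_scaling_study()`)
preallocates every output buffer before starting a monotonic clock, so the
measured quantity is the zip work itself, repeated enough times per
measurement (calibrated, default window 10 ms) to make sub-millisecond
traversals measurable, with the median of `repeats` windows reported.

## Input handling

FASTA parsing (via Biostrings) expands IUPAC ambiguity codes into symbol
sets when the alphabet supports them. Gap characters in input sequences are
rejected by default — the tool consumes unaligned sequences; `degap = TRUE`
strips them (the path used when slicing existing alignments back into
inputs), and `keep_gap_symbol = TRUE` admits the character as an ordinary
residue for alphabets that treat `-` as a fifth symbol. Newick parsing (via
ape) keeps child order as written, ignores branch lengths and inner labels,
and rejects polytomies rather than auto-rooting: with a non-associative
operator, rooting is a modelling choice the user must make explicitly.
Leaves lift to `BOTH(X, X)` elements — a leaf has no subtree asymmetry and
the lift must carry the residue set through the effective-set projection
unchanged; the form of the leaf lift is otherwise unconstrained.

Alphabets are limited to 30 symbols (bitset representation); at least three
symbols including the gap are required, as in the underlying formalism.
Integer cost matrices are exact in double arithmetic at these magnitudes;
fractional matrices use an equality tolerance of 1e-9 for tie detection in
medians and tracebacks.

## The pathological generator and what it does (not) show

`generate_pathological(k, n, mode)` builds the benchmark family: `n/4`
quartets, each carrying `A^k`, `C^k`, `G^k`, `T^k`, joined into a balanced
binary tree. (A published description of this construction gives the
quartet count as `2^(n/4)`, which is dimensionally inconsistent with a
balanced tree of `n` leaves; the generator uses `n/4`.) `mode = "perfect"`
pairs the data with the substitution-preferring matrix `sigma0`, collapsing
the alignment to `m = 1`; `mode = "degenerate"` pairs it with the
indel-preferring `sigma1`, driving it to `m = n`. The generator is fully
deterministic; its seed argument only shuffles leaf names.

The scaling study fits `log2(runtime) = β0 + β1·log2(n) + β2·log2(k) + ε`
by OLS (`fit_loglog()`), recovering exponents exactly on noiseless
power-law data. The acceptance checks run the grid `n ∈ {4,…,64}`,
`k ∈ {16,…,256}` (geometric steps) and assert exponent *bands* —
`β1 ≈ 1` (perfect) vs `β1 ≈ 2` (degenerate), `β2 ≈ 1` in both — rather
than exact published coefficients, which are hardware-mediated. These sizes
keep the whole study to a few seconds while spanning a 16-fold range in
each dimension; the regimes are asymptotic statements, and the bands are
wide enough to absorb small-size curvature (at `n = 4` the quadratic
regime's local slope already exceeds 2 slightly because the node count
`2n−2` is not proportional to `n`).

The pathological data are extremes by construction. Passing these checks
shows the implementation reaches both complexity regimes and respects the
structural invariants (equal row lengths, input recovery on degapping, no
all-gap columns, cost conservation, label invariance under child
transposition) on random trees with random sequences. It does **not** show
anything about alignment *quality* on real molecular data: implied
alignment is a heuristic for the NP-hard tree alignment problem, is neither
optimal nor unique, and real-data behaviour interpolates between the
regimes as sequence similarity varies. `degrade_dataset()` supports the
corresponding real-data experiment — repeatedly halving a user-supplied
tree and taking central, degapped slices of a user-supplied alignment to
produce nested doubling instances — but ships no biological data.

## Degenerate inputs and numerical corner cases

* Empty sequences decorate to empty contexts with a warning; an all-gap
  slice in `degrade_dataset()` likewise warns and yields an empty string.
* A two-leaf tree reproduces exactly the pairwise alignment.
* `m` is reported to four decimals; tree costs are reported as integers
  whenever the cost matrix is integral.
* Output rows are rendered with IUPAC codes where possible, set notation
  (`[AG]`) otherwise; set notation widens columns and is meant for
  inspection, not round-tripping.

## Known limitations

* No affine or logarithmic-affine gap costs, and no banded/low-memory
  pairwise variants: the full `Θ(L²)` matrix is the default and only
  engine. The worst-case post-order on large degenerate inputs is the
  memory bound (one byte per matrix cell for the traceback).
* No NEXUS/PHYLIP dialects, no tree search, no rooting heuristics.
* Amino-acid alphabets work (any alphabet up to 30 symbols with a gap),
  but no residue-specific defaults are bundled.
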