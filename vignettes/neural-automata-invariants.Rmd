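---
title: "Neural automata and recoding-invariant observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural automata and recoding-invariant observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurautomata)
```

## The problem

Neurosymbolic models of cognition embed symbolic computation — parsing a
sentence, running an automaton — into a real phase space, so that model
trajectories can be regressed against physiological measurements (ERPs, BOLD,
reading times). The embedding used here is the Gödel encoding: order the
alphabet by a bijection $\gamma: \mathbf{A} \to \{0,\dots,m-1\}$ and map a
symbol string $a_1 a_2 \dots$ to

$$\psi_\gamma(s) = \sum_k \gamma(a_k)\, m^{-k} \in [0,1].$$

The ordering $\gamma$ is completely arbitrary. Any observable computed from
the resulting trajectories therefore mixes two things: structure intrinsic to
the symbolic dynamics, and artefacts of the chosen code. This package makes
that distinction computable. It implements the full pipeline — symbol
sequences, rewriting machines, their compilation to piecewise affine maps on
the unit square and further to recurrent networks — together with the
symmetry analysis: which macroscopic observables are invariant under *Gödel
recodings* (permutations $\pi$ with $\pi \circ \gamma_1 = \gamma_2$), and
which are not.

The central combinatorial object is the **pattern of equality** of a word:
the set partition of its positions induced by symbol identity
(`pattern_of_equality()`). A recoding can map a word $w$ onto $u$ exactly
when $|w| = |u|$ and the patterns agree; the patterns therefore classify the
orbits of words, of cylinder intervals, and of rectangle cells in the unit
square. Step functions that are constant on those orbit classes are invariant
under every recoding; essentially nothing else is — in particular the Amari
mean network activity is not.

## Exact arithmetic

Gödel numbers, cylinder endpoints and affine coefficients all have
denominators $m^k$. Membership in the half-open cells
$[i/m^l, (i+1)/m^l)$ must be decided exactly — a float that lands a hair's
breadth on the wrong side of a boundary silently corrupts a trajectory — so
every quantity upstream of the neural network is an exact rational
(`rational()`): integer numerator and denominator held in doubles, reduced,
with a hard error beyond $2^{53}$ where double integer arithmetic would stop
being exact. Floating point appears only inside the network layer, whose
comparison against the exact trajectory uses a tolerance of $10^{-9}$.

Two conventions keep the encoding well defined:

* **Half-open intervals** $[k/m^n, (k+1)/m^n)$ throughout, so the depth-$n$
  cylinder intervals partition $[0,1)$.
* **Finite words with implicit blank padding.** Only finite words are
  encoded; the bi-infinite tape is the word padded with blanks. Since no
  encoded value ends in an infinite tail of $(m-1)$s, every value has a
  unique expansion and decoding is exact.

A third convention, **blank anchoring**, forces the blank symbol to code 0 in
an encoding (`godel_encoding(..., anchored = TRUE)`). Without it, padding
would contribute to the Gödel number and strings of different lengths would
collide under recoding. Anchoring is a flag rather than hard-wired: the
orbit-enumeration examples use the full symmetric group, while everything
that touches machines (where tape lengths vary) requires anchored encodings
and the blank-fixing subgroup $S_{m-1}$.

The displayed boundary metric in our source material swaps its 0 and 1
cases; as stated it would violate both the ultrametric axioms and the
interval co-membership property. `tree_distance()` implements the standard
orientation (0 for equal rays, 1 for disagreement at the first symbol,
$m^{-n}$ for an exactly-$n$ shared prefix), under which both properties are
verified by the test suite.

## Machines

A **versatile shift** (`versatile_shift()`) rewrites dotted sequences: the
window of $k_l$ stack and $k_r$ input symbols around the dot (the *domain of
dependence*) is matched against an ordered rule list, the first matching
rule substitutes a dotted word of arbitrary length, and the dot may shift.
Wildcards (`"?a"`) bind single non-blank symbols, which is what the attach
rule of a recognizer needs (`a.a -> .` with a shared variable) and what keeps
rules from firing on empty tape. First-match order makes stepping a
function; the grammar machines' rules are mutually exclusive, so order is
immaterial there. A run is *accepted* when the tape empties, *rejected* when
no rule matches, and otherwise cut off by the step budget (the only guard
against left-recursive grammars).

`build_topdown_recognizer()` compiles a context-free grammar into the
standard predict/attach machine with DoD $(1,1)$: each production
$X \to Y_1 \dots Y_p$ becomes a predict rule replacing stack-top $X$ by the
right-hand side with $Y_1$ adjacent to the dot (the stack is stored
dot-outward, hence "reversed"), and a single attach rule cancels equal
stack-top and input terminals. Lexical rules are folded into the terminals:
the demo grammar `S -> NP VP`, `VP -> V NP` parses the pre-tokenized
sentence `NP V NP` in five steps.

## From machine to unit square to network

Under a pair of anchored encodings, `build_nda()` compiles a versatile shift
into a *nonlinear dynamical automaton*: the unit square is cut into
$m_\text{left}^{k_l} \times m_\text{right}^{k_r}$ DoD cells, and on each
cell with a matching rule the action on the Gödel numbers is the diagonal
affine map forced by the conjugacy requirement
$\psi(\text{step}(s)) = \Phi(\psi(s))$: if the rule consumes prefix $u$ and
writes $v$ on an axis of base $m$, then $\lambda = m^{|u| - |v|}$ and
$a = \psi(v) - \lambda\,\psi(u)$. Because the cell is determined only by the
DoD digits, one branch serves all tape remainders — this is exactly why
$\lambda$ is a pure power of $m$. Cells without a matching rule carry no
branch and form the halting region; consequently the NDA halts at precisely
the times the symbolic machine does, which the suite checks exactly, for the
demo and for fleets of random machines. Rules with a nonzero dot shift are
rejected at compile time: moving a symbol across the dot couples the two
coordinates and has no diagonal affine form. Pure-shift machines remain
available at the symbolic level through `compile_generalized_shift()`.

`build_na()` realizes the NDA as a recurrent network. The design decisions,
where the construction was genuinely open, are:

* **Three layers, five units per branch group.** Two MCL units carry
  $(y_1, y_2)$. Each branch group has two BSL threshold detectors
  ($y_1 \ge \text{lo}_1$, $y_2 \ge \text{lo}_2$), one BSL gate, and two LTL
  saturated-linear units computing the gated affine image. Upper-bound tests
  reuse the lower detectors of neighbouring cells — cell $[i/m, (i+1)/m)$
  needs the detector of $i+1$, which some branch already owns — so no
  dedicated upper units exist; the topmost intervals need no upper test at
  all because activations stay below 1.
* **Hardware for every cell except the accepting one.** Branch groups are
  laid out uniformly over the partition, independent of the rule set: cells
  with no rule get the identity transformation (a "stall"). The unit count
  is therefore a function of the partition geometry alone,
  $n = 2 + 5(\text{cells} - 1)$. The demo recognizer has $5 \times 3 = 15$
  cells, giving $n = 2 + 5 \cdot 14 = 72$ units. The accepting (all-blank)
  cell carries no hardware: no transformation is ever applied there, and
  "no gate fires" *is* the network's accept signal.
* **Halting.** `na_macro_step()` signals a halt when no gate fires (accept)
  or when the active branch is a stall cell (reject), so network traces
  agree step-for-step with the NDA and the symbolic trace.
* **Macro-step sampling.** Observables are evaluated at macro-step
  boundaries; the BSL/LTL entries of a state are the values computed during
  the transition into it (zeros at $t=0$).
* **Numerics.** Weights are stored exactly and executed in floating point.
  Detector thresholds carry a margin of $10^{-12}$: float error is
  $\sim 10^{-15}$ while legitimate Gödel numbers stay at least one fine-grid
  spacing ($\ge 10^{-11}$ at the tape lengths the fixtures allow) away from
  the boundaries they do not sit on. `read_mcl()` snaps activations back to
  the rational grid at tolerance $10^{-9}$.

## Observables and the symmetry

A recoding pair $\pi = (\pi_1, \pi_2)$ of blank-fixing code permutations
acts on the square by relabeling the corner digits of each partition cell
and translating the cell rigidly (`rho_pi()`); on observables by pullback,
$\alpha_\pi(f) = f \circ \rho_\pi$ (`alpha_pi()`), a group representation.

`build_step_observable()` constructs the invariant observable: at resolution
$(l, r)$ it classifies every rectangle cell by the pair of blank-anchored
patterns of equality of its corner digit words and assigns one coefficient
per class, drawn (distinct) from a seeded uniform generator — the
coefficients are arbitrary by design, so runs are comparable only through
the class structure, not through particular values. Per-axis keys are the
default and the only choice invariant under the product group
$S_{m_1-1} \times S_{m_2-1}$, which is the symmetry that actually applies
when stack and input alphabets differ in size (the demo uses sizes 5 and 3);
the joint mode (one shared permutation, equal sizes) exists to reproduce the
worked single-alphabet example. Finer resolutions give sharper invariants;
$(l, r) = (2, 3)$ matches the demo's stack and input depths.

```{r demo}
d <- demo_bundle()
verify_invariance(d$vs, d$input, d$encodings, "step", l = 2, r = 3)
verify_invariance(d$vs, d$input, d$encodings, "amari")
```

The step series agree exactly (difference 0) across the two printed
encodings, while the Amari mean differs from the very first state — its
value depends on the MCL coordinates, hence on the code. Harmony (with the
network's own weight matrix) and dissimilarity are provided for the same
kind of comparison.

## What the random fixtures emulate — and what they do not

`random_vs()` generates small machines for the property suites: alphabets of
size at most 3 per side, DoD $(1,1)$, up to 4 literal rules, replacements of
at most 2 symbols per side, no dot shift. These bounds are not incidental:
they keep tape lengths, and hence Gödel denominators, within exact double
range over 20-step runs, so the conjugacy suite can assert *exact* equality.
The fixtures thus probe the compilation logic (rule matching, cell geometry,
affine coefficients, halting) across many machine shapes. They do not probe
large alphabets, deep windows, wildcard-heavy rule systems, or long
runs — passing tests certify the construction on the regime the theory's
worked examples occupy, not scalability. Orbit and partition enumeration
grows factorially in the alphabet size and exponentially in depth, a
practical constraint inherited by any user of sharp invariants.

Problem sizes used by the suites (chosen once, as the package's own test
design): orbit-versus-oracle enumeration exhaustive for $m \le 4$,
$l \le 6$, with the oracle evaluated once per pattern class; round-trip
encoding exhaustive for $m \le 4$, $l \le 4$ plus seeded random words to
$l = 8$, $m = 5$; ultrametric axioms exhaustive over all words of length
$\le 3$ at $m = 3$ plus random length-5 triples; conjugacy on the demo and
50 seeded machines over 20 steps; step-observable invariance over every
blank-fixing pair for axis sizes $(3,3)$, $(3,5)$, $(5,3)$ on $10^3$ random
grid points.

## Limitations

* No general dot-shift Gödelization: $F \ne 0$ machines run symbolically but
  do not compile to NDAs.
* No learning: network weights are compiled, never fitted; leaky-integrator
  and logistic-rate dynamics are out of scope.
* Orbit classes, not orbit values: step-observable *values* depend on the
  coefficient seed; only their equality structure is meaningful.
* The exact-rational layer is bounded by $2^{53}$; very long tapes or deep
  partitions need arbitrary-precision arithmetic the package deliberately
  does not depend on.
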