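---
title: "Driver, sensor and dual-identity nodes: model, theory, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver, sensor and dual-identity nodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(controbs)
```

## The model

A directed network on $N$ nodes with $M$ edges is read as the zero/nonzero
pattern of a state matrix $A$ of a linear time-invariant system
$\dot X = AX + BU$, $Y = CX$: an edge $x_j \to x_i$ means $a_{ij} \neq 0$,
with the entries treated as independent free parameters (the *structural*
setting). Structural controllability asks for the smallest input set $B$
that makes the system controllable for generic parameter values; structural
observability is its dual under edge reversal.

Both questions reduce to one matching problem. The bipartite representation
$H(A)$ has a left copy $x_i^l$ and a right copy $x_i^r$ of every node and
one undirected edge $(x_j^l, x_i^r)$ per directed edge. Given any maximum
matching of $H(A)$:

* a node is a **driver** iff its right copy is unmatched — it heads no
  matched edge, so an independent input must drive it;
* a node is a **sensor** iff its left copy is unmatched — dually, an
  independent output must read it;
* **dual-identity (DS)** iff both copies are unmatched; **ordinary** iff
  neither.

Driver and sensor counts both equal $N - |\mathcal M|$, which is why
$n_D = n_S$ on *every* input, exactly. With overlapping driver/sensor sets
the fractions satisfy $n_D + n_S - n_{DS} + n_O = 1$; with exclusive sets,
$n_{D,\mathrm{only}} + n_{S,\mathrm{only}} + n_{DS} + n_O = 1$. Both
identities are asserted property-style over hundreds of random graphs in
the test suite.

### The perfect-matching convention

When a perfect matching exists, the literal reading of the matching
criterion flags *no* node, and `classify_nodes()` reports every node as
ordinary ($n_O = 1$). The minimum-input theory still requires one input
(attachable to any node) to control such a network. We keep the literal
reading as the default because it is the only one consistent with the
fraction accounting above; `lemma1_convention = TRUE` promotes the first
node in node order to driver (and sensor) for users who want the
minimum-input count instead.

### Matching non-uniqueness

$n_D$ is matching-invariant; the DS/ordinary split is not — different
maximum matchings can leave different *nodes* doubly unmatched. The default
is deterministic (left copies processed in first-appearance order inside
Hopcroft–Karp), so a given input always yields the same report.
`node_roles(g, resamples = R, seed = s)` re-matches under $R$ random left
orders and reports mean ± sd of $n_{DS}$ and $n_O$. In practice the spread
is small (sd $\sim 10^{-3}$ on ER networks with $N = 10^4$), so a single
matching is representative of the counts even though the member sets
differ.

## Generators: the stated world

`generate_er(n, m)` draws exactly `m` distinct ordered pairs of distinct
nodes uniformly — the directed $G(N, M)$ ensemble, no self-loops, whose
in/out degrees are asymptotically Poisson with mean $\langle k\rangle =
M/N$. `generate_sf(n, m, a_in, a_out)` is the *static model*: node $i$
carries source weight $i^{-a_\mathrm{out}}$ and target weight
$i^{-a_\mathrm{in}}$; edges are drawn weight-proportionally and rejected if
repeated or self-looping, giving power-law in/out tails with exponent
$\gamma = 1 + 1/a$. Self-loops are excluded in both models (the ER
construction selects two distinct nodes; we treat the SF model the same way
for consistency, since a self-loop would trivially match a node's own two
copies). The SF draw budget is $100\,M$ attempts before a convergence
error; dense, strongly skewed parameter choices can stall on rejections.

`rewire_degree_preserving()` is the null model isolating the degree
sequence: repeated double-edge swaps $(a,b),(c,d) \to (a,d),(c,b)$,
rejecting self-loops and duplicates, with a default of $10M$ successful
swaps (a standard mixing heuristic; the swap count is not critical past a
few multiples of $M$). Every node keeps its exact in- and out-degree.

What the generated worlds do *not* emulate: degree–degree correlations,
reciprocity, modularity, or self-loops of real networks. A green ensemble
test therefore establishes agreement between theory and *uncorrelated*
random graphs with the designed degree distributions — not agreement with
any particular real network. Note also a finite-size caveat used when
sizing one acceptance check: static-model graphs at $N \approx 2000$,
$\gamma = 3$ retain enough structural (dis)assortativity that rewiring
shifts $n_D$ by $\approx 0.01$; the shift decays to $\approx 0.002$ by
$N = 5000$, so asymptotic degree-sufficiency checks are run at
$N \geq 5000$ for SF inputs.

## The analytic theory

Greedy leaf removal (GLR) on $H(A)$ repeatedly removes a degree-one node
(*leaf*) with its sole neighbor (*root*), adding the connecting edge to a
matching; what survives with degree $\geq 2$ is the *core*. On locally
tree-like random graphs the probabilities $\alpha^\pm$ (edge endpoint
becomes a leaf) and $\beta^\pm$ (becomes a root) satisfy, with
$Q(k^\pm) = k^\pm P(k^\pm)/\langle k\rangle$,

$$\alpha^\pm = \sum_{k \geq 1} Q(k^\pm)\,(\beta^\mp)^{k-1}, \qquad
  \beta^\pm = 1 - \sum_{k \geq 1} Q(k^\pm)\,(1-\alpha^\mp)^{k-1}.$$

From the fixed point, the per-side core fractions and the root fraction are

$$n_c^\pm = \sum_k P(k^\pm)\left[(1-\alpha^\mp)^k - (\beta^\mp)^k\right]
  - \langle k\rangle\,\alpha^\pm\,(1-\alpha^\mp-\beta^\mp),$$
$$n_r = \Big[1 - \sum_k P(k^+)(1-\alpha^-)^k\Big]
  + \Big[1 - \sum_k P(k^-)(1-\alpha^+)^k\Big]
  - \langle k\rangle\,\alpha^+\alpha^-,$$

and the maximum matching splits into root-contributed and core-contributed
edges, giving

$$n_D = n_S = 1 - \big(n_r + \min\{n_c^+, n_c^-\}\big).$$

The DS fraction is estimated by leaf/isolate counting: isolated nodes are
always DS, and in-/out-leaves (degree patterns $(1,0)$ and $(0,1)$)
sharing a neighbor usually are, which motivates

$$n_{DS} \approx P(0^-)P(0^+) + P(0^-)P(1^+) + P(1^-)P(0^+).$$

This estimate is *heuristic*: it counts every leaf, not only the ones a
maximum matching actually leaves doubly unmatched. On ER ensembles at
$N = 10^4$ it is accurate to $< 0.05$ for $\langle k\rangle \geq 2$ but
overshoots by $\approx 0.15$ at $\langle k\rangle = 1$ (simulated
$n_{DS} \approx 0.205$ vs $3e^{-2} \approx 0.406$), where single leaves
abound but rarely stay doubly unmatched. The corresponding acceptance check
is left failing at $\langle k\rangle = 1$ rather than widened: the
ensemble-level deviation is a property of the estimate itself. The ordinary
fraction for arbitrary distributions is derived from the accounting
identity $n_O = 1 - 2 n_D + n_{DS}$ rather than from a separate formula.

### Closed forms

*Poisson (ER).* $P(k) = e^{-\langle k\rangle}\langle k\rangle^k/k!$ on both
sides makes the fixed point symmetric ($\alpha = \alpha^\pm$,
$\beta = \beta^\pm$) and the DS estimate collapses algebraically to
$n_{DS}^{ER} = e^{-2\langle k\rangle}(2\langle k\rangle + 1)$. The ordinary
fraction closed form
$n_O^{ER} = n_{DS}^{ER} - 2[\alpha - \beta +
\langle k\rangle\alpha(1-\beta)] + 1$ is the accounting identity in
disguise: the bracket equals the fixed-point driver fraction under the
Poisson law (verified numerically to $10^{-9}$ across
$\langle k\rangle \in [0.5, 8]$ in the tests).

*Static model (SF).* With $a = 1/(\gamma-1)$, $c = \langle k\rangle(1-a)$,
the degree law is $P(k) = \delta\,\Gamma(k - 1/a, c)/\Gamma(k+1)$ with
$\delta = c^{1/a}/a$. The normalization is exact:
$\sum_k \Gamma(k-1/a, c)/k! = a\,c^{-1/a}$ (sum the defining integrals and
use $\sum_k t^k/k! = e^t$), and the mean is $c/(1-a) = \langle k\rangle$.
The DS closed form is $n_{DS}^{SF} = \delta^2\Gamma_0^2 +
2\delta^2\Gamma_0\Gamma_1$ with $\Gamma_k = \Gamma(k-1/a, c)/\Gamma(k+1)$ —
again the leaf/isolate estimate evaluated at $P(0), P(1)$ — and the
ordinary closed form uses incomplete-gamma ratios
$C_i = \Gamma(-1/a, z)/\Gamma(1-1/a, z)$ at $z = c\alpha$ and
$z = c(1-\beta)$.

## Numerical choices

* **Fixed point.** Plain alternating iteration from
  $\alpha^\pm = \beta^\pm = 0$ (first the $\alpha$ map, then the $\beta$
  map using the fresh $\alpha$), tolerance $10^{-12}$ on the max coordinate
  update, cap $10^5$ iterations, values clamped to $[0,1]$. The iteration
  is monotone-stable in practice; non-convergence raises an error carrying
  the last iterate. The edgeless limit $\langle k\rangle = 0$ is handled
  exactly ($\alpha = 0$, $\beta = 1$, so $n_D = 1$), and the near-isolated
  limit was checked numerically at $\langle k\rangle = 10^{-6}$
  ($n_D \to 1$).
* **Series truncation.** Empirical distributions use the observed maximum
  degree. Parametric distributions truncate where the tail mass drops below
  $10^{-12}$, capped at $k = 10^4$. For heavy tails ($\gamma = 2.5$) the
  cap binds; the residual tail mass is folded into the last bin so that
  $P(0)$ and $P(1)$ — which drive the DS estimate — remain exactly
  parametric, and the truncated mean stays within 1% of
  $\langle k\rangle$.
* **Upper incomplete gamma at $s \leq 0$.** Standard routines refuse
  negative first arguments, so $\Gamma(s,x)$ is computed by the downward
  recurrence $\Gamma(s,x) = (\Gamma(s+1,x) - x^s e^{-x})/s$ from a positive
  starting point, stepping on integer offsets from $s$ (stepping on a
  floating accumulator can run one extra iteration and is catastrophically
  wrong near $s \to 0^-$), with $\Gamma(0,x) = E_1(x)$ via a power series
  ($x \leq 1$) or modified Lentz continued fraction ($x > 1$). Validated
  against adaptive quadrature on a grid of $(s, x)$ in the tests. Inside
  the SF degree law the ratios $\Gamma(k-1/a,c)/k!$ are propagated by the
  *upward* recurrence with the correction term computed in log space, which
  is overflow-free to $k = 10^4$.
* **Matching determinism and tie-breaks.** Hopcroft–Karp processes left
  nodes in a caller-supplied order (default: first-appearance), both when
  seeding BFS layers and when augmenting, so runs are reproducible; the
  matching *size* is order-invariant (asserted over random permutations).
  GLR processes leaves in node order (left copies before right); root and
  core *sizes* are tie-break-invariant, and only sizes enter the theory.
* **Degenerate inputs.** Empty graphs classify to an empty assignment but
  have undefined fractions ($N = 0$ errors); empty categories in degree
  statistics report `NA`, never a fake 0; duplicate edges collapse with a
  message (structural matrices only record $a_{ij} \neq 0$); self-loops are
  kept and map to $(x_i^l, x_i^r)$.

## Design decisions taken where the design was open

* **Brute-force oracle.** The test oracle for matching is an exhaustive
  backtracking search over left nodes (refusing $> 20$ edges), independent
  of Hopcroft–Karp's augmenting-path machinery; the suite also
  cross-checks against igraph's matcher. Exhaustive enumeration over all
  digraphs with $N \leq 3$ (with self-loops) and $N = 4$ (without) plus 200
  random $N \leq 6$ digraphs ties the two routes together.
* **ER sampling.** Drawing $M$ ordered pairs without replacement from the
  $N(N-1)$ admissible ones is distribution-identical to the sequential
  insert-with-rejection construction and much faster; the SF generator
  keeps the sequential rejection semantics because its draw distribution is
  non-uniform.
* **Seeds.** Generators take an explicit `seed` and call `set.seed`;
  the CLI defaults to seed 0 and echoes it in every JSON summary, making
  artifacts byte-reproducible.

## Known limitations

* The DS estimate is heuristic (see above); do not use it below
  $\langle k\rangle \approx 2$ if absolute accuracy matters — classify and
  count instead.
* The fixed-point theory assumes uncorrelated, locally tree-like networks;
  degree–degree correlations (present in many real networks and in small
  static-model samples) shift $n_D$ beyond the theory's reach.
* No edge classification (critical/redundant), no enumeration of all
  maximum matchings, no control-energy or time-to-control analysis.
* Real-network benchmarks (regulatory networks, connectomes, food webs)
  must be supplied by the user as edge lists; the package bundles no
  third-party data.
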