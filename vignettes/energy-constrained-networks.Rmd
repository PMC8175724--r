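---
title: "Energy-constrained network formation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-constrained network formation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connergy)
```

## The model

`connergy` simulates the formation of a weighted, signed, generally
asymmetric network of $N$ nodes described by a connectivity matrix
$W = (w_{ij})$. Nodes stand for neurons or brain regions; a signed weight
encodes an excitatory or inhibitory connection. The guiding hypothesis is
that network structure emerges from pressure to use energy efficiently,
formalized through two per-node costs:

* **wiring cost** — the energy of building and maintaining connections,
  $E_w(i) = \sum_j |w_{ij}|$;
* **activity cost** — the energy of signal transfer through the node.
  An input state $V^0 \in \{-1, 0, +1\}^N$ is propagated one step,
  $v_i = \sum_j w_{ij} v^0_j$, and the cost sums the absolute
  contributions of each connection under that activation,
  $E_a(i) = \sum_j |v_i\, w_{ij}\, v_j|$, averaged over a batch of input
  states. This is a Hopfield-like interaction energy taken in absolute
  value, since metabolic expenditure is positive regardless of sign.

The training objective is the node-averaged **normalized energy**
$\langle E_a(i) / E_w(i) \rangle$, the energy consumed by activity per
unit of wiring investment. Minimizing the ratio rather than $E_a$ alone
rewards strengthening connections at highly activated nodes — an
activity-dependent refinement loosely analogous to synaptic plasticity.

### Which activation enters the partner term

The displayed cost uses one symbol for both activation factors. Reading
both $v_i$ and $v_j$ as the *propagated* state is the literal
interpretation and is the default (`activity_form = "post_post"`). The
alternative, with the partner factor taken from the pre-transition input
($|v_i\, w_{ij}\, v^0_j|$), is provided as `"post_pre"`; the gradient is
exact for both. The two forms give the same qualitative behavior in our
tests; no claim is made about which was "intended".

## Constraints

Unconstrained, the ratio can be driven to zero through two unphysical
channels: diverging weights ($E_w \to \infty$) or a silent network
($E_a \to 0$). Two constraints block them.

* **Upper weight bound.** After each epoch's updates the bound
  $w_u = \langle |w| \rangle + n_\sigma\, \sigma(|w|)$ is recomputed from
  the current matrix (population standard deviation over all $N^2$
  entries) and entries with $|w| > w_u$ are clipped to $\pm w_u$.
  `n_sigma = NULL` gives the unbounded ("no-limit") condition.
* **Activity floor.** Before training, the node-averaged activity cost
  $E_a^0$ of the initial random matrix is measured on a fixed probe
  batch. Whenever the current probe activity falls below
  $E_a^L = \alpha E_a^0$, every weight is multiplied by $E_a^L / E_a$ —
  a homeostatic scaling-up of all synapses. Because $E_a$ is homogeneous
  of degree 3 in $W$, an upward rescale by $r$ multiplies $E_a$ by $r^3$,
  so the rule overshoots the floor; it is applied exactly as stated since
  the overshoot still serves the constraint's purpose (prohibiting the
  zero state).

Order matters: clipping can only lower $E_a$, so the floor check runs
after the clip. A consequence worth noting: when the floor fires, the
uniform rescale multiplies the just-clipped weights above the clip bound
used that epoch. Both the bound definition and the rescale are
scale-covariant, so the invariant the epoch-end matrix satisfies is
$\max |w| \le w_u \cdot r$ with $r$ the rescale factor; the trace records
`w_u`, `max_abs_w` and `floor_rescale` so this is checkable per epoch.

The default $\alpha = 10^{-3}$ is the value used for the main comparisons
in the source protocol; the published description lists slightly
different $\alpha$ sets in two places, so $\alpha$ is exposed as a free
parameter rather than fixed.

## Training protocol

`refine_network()` runs, per epoch:

1. normalize $W \to W / \langle |W| \rangle$. The scalar is the mean of
   *absolute* values: a signed mean sits near zero for a centered weight
   distribution and would make the division explode, so the absolute mean
   is a deliberate deviation from a literal signed reading;
2. split the signal pool ($10^4$ vectors by default) into 10 random
   batches without replacement and take one Adam step per batch on the
   exact analytic gradient of the objective (derived by hand; absolute
   values use subgradient 0 at 0, so exactly-zero weights are stationary
   for the direct term). Because $W$ is asymmetric, the same refinement is
   applied to $W^T$: by default each batch performs a second Adam update
   on the transposed objective with its own optimizer state
   (`transpose_mode = "sequential"`); a symmetrized-gradient variant
   (`"averaged"`) and `"off"` are available. Adam uses its canonical
   $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$ with learning
   rate 0.01;
3. restore the scale with the same constant;
4. apply the clip and then the floor, and record the objective on the
   fixed probe batch (the first pool batch), so trace values are
   comparable across epochs.

Input signals model homogeneous external drive: per vector, a sparseness
$p \sim U(0, 0.5)$ is drawn, then each element is $\pm 1$ with total
probability $p$ (split evenly) and 0 otherwise. "Nonzero with probability
$p$, sign uniform" is the default reading; the alternative (each sign
independently with probability $p$) is available as
`sign_scheme = "independent"`. One $p$ per vector, drawn once when the
pool is generated; epochs resample batches from this fixed pool.

All randomness derives from the single `seed` in `simulation_config()`,
so runs are bit-reproducible on one platform; across platforms agreement
is only to floating-point tolerance.

## Network statistics

* `stability_rmse()` — flatten each network, sort $|w|$ descending,
  divide by the mean; average the RMSE between ordered vectors over all
  unordered pairs. Sorting by absolute value keeps the notion of
  "strength" consistent with every other statistic here.
* `strength_distribution()` — node strengths $s_i = \sum_j |w_{ij}|$
  sorted descending, sampled at 100 ranks nearest $((n+1)/101) N$,
  max-normalized, and paired with cumulative probabilities $(n+1)/101$.
  Inputs smaller than 100 use every value. Repeated runs of one condition
  are pooled before sampling.
* `cluster_curve()` — for each connection ratio $r$ on a 0.01 grid, keep
  the top $\lfloor r\, n_c \rfloor$ connections by $|w|$ ($n_c$ = nonzero
  off-diagonal count; ties broken by row/column index for determinism)
  and record the maximum number of distinct partners of any single node,
  counting either direction once. Curves are normalized by the $r = 1$
  value — "the full network" reading of the normalization reference,
  chosen so curves of different-sized networks are comparable. The
  alternative reading (the pre-training random matrix) would make
  trained/initial comparisons circular, which is why it was rejected.
  Self-connections are excluded throughout.
* `degree_product_weights()` — binary topological networks get surrogate
  weights $w_{ij} = d_i d_j$ on existing edges so strength-based
  selections apply; absolute-value selection on signed matrices is used
  for the same consistency reason as in the stability metric.

## The synthetic connectome generator

`synth_connectome()` exists so comparison pipelines can be exercised
offline. It draws node propensities $u_i = e^{h z_i}$, $z_i \sim N(0,1)$,
Bernoulli connection existence at the requested density, and weights
$u_i u_j |\varepsilon|$. `hubness` $h = 0$ yields near-uniform strengths
(coefficient of variation $< 0.3$ at $N = 200$); larger $h$ yields
heavy-tailed strength profiles like real connectomes. It reproduces only
the *strength dispersion* aspect of connectome data — not spatial
embedding, modular organization, distance-dependent wiring, or realistic
sparseness patterns — so tests passing on it say nothing about those
features. Real connectome matrices are supplied by the user as dense CSV
or edge-list files.

## Problem sizes and numerical choices

The full protocol ($N = 200$, 200 epochs, $10^4$ signals) runs in about
two minutes on one CPU, so convergence behavior and the trained-versus-
random cluster comparison are checked directly at that scale. The
multi-seed comparisons (stability, strength pooling, per-epoch constraint
checks) use a reduced condition of $N = 50$ and 50 epochs with the full
signal pool and 5 independent seeds per condition, which preserves every
element of the protocol while keeping one run in the seconds range;
statistics are run-averaged or pooled across seeds, mirroring the
many-iteration protocol at smaller replication.

Plateau detection genuinely needs the full 200-epoch horizon: once the
activity floor engages (around epoch 35-40 at $N = 50$, epoch 25-35 at
$N = 200$), the probe objective keeps creeping downward by several
percent per 10-epoch bin for a while, because the weight distribution
continues to sharpen under the scale-covariant bound. A 50-epoch run
stops inside that transient; by epoch 200 the binned curve is flat to a
fraction of a percent per bin.

Degenerate inputs are handled explicitly: a node whose wiring cost is
exactly zero is excluded from the objective with a warning (it can arise
only after clipping to $w_u = 0$); an exactly zero activity state with a
positive floor is an unrecoverable collapse and raises an error, as no
finite rescale can leave the zero state; non-finite weights or objectives
abort with the epoch index.

## Limitations

The model is a single-layer, fully connected, one-step-propagation
abstraction: no spiking dynamics, no Dale's-law sign constraints, no
per-node connection-count limits, no multilayer hierarchy, and
homogeneous random input rather than structured stimuli. Comparisons with
real connectomes are statistical (strength distributions, cluster
curves), not anatomical.
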