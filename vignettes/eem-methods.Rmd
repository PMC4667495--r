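---
title: "EEM charges: model, parameterization and design notes"
author: "EEMCharges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEM charges: model, parameterization and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The Electronegativity Equalization Method (EEM) assigns conformationally-
dependent partial atomic charges to a molecule with known 3D structure by
requiring all effective atomic electronegativities to equalize at a common
molecular value $\bar\chi$ while the charges sum to the total molecular
charge $Q$.  For $N$ atoms this is one linear system,

$$
\begin{pmatrix}
B_1 & \kappa/R_{1,2} & \cdots & \kappa/R_{1,N} & -1 \\
\kappa/R_{2,1} & B_2 & \cdots & \kappa/R_{2,N} & -1 \\
\vdots & & \ddots & & \vdots \\
\kappa/R_{N,1} & \kappa/R_{N,2} & \cdots & B_N & -1 \\
1 & 1 & \cdots & 1 & 0
\end{pmatrix}
\begin{pmatrix} q_1 \\ q_2 \\ \vdots \\ q_N \\ \bar\chi \end{pmatrix}
=
\begin{pmatrix} -A_1 \\ -A_2 \\ \vdots \\ -A_N \\ Q \end{pmatrix},
$$

where $R_{i,j}$ are interatomic distances in Angstrom, $A_i$ (effective
electronegativity) and $B_i$ (effective hardness) are empirical per-atom-type
parameters, and $\kappa$ is one global constant screening the $1/R$
interaction.  An atom type is the element symbol plus the maximal bond order
over the atom's bonds (`C2` = carbon with at least one double bond); aromatic
input bonds are normalized to order 2 at parse time, so aromatic atoms fall in
the `X2` types.  No aromaticity or bond-order perception is ever run — only
explicit annotations in the input are trusted.

The atom rows are exactly the stationarity conditions of the quadratic energy
$E(q) = \sum_i (A_i q_i + \tfrac12 B_i q_i^2)
       + \tfrac{\kappa}{2}\sum_{i \ne j} q_i q_j / R_{ij}$
on the plane $\sum_i q_i = Q$, with $\bar\chi$ as the Lagrange multiplier.
The test suite exploits this: an independent conjugate-gradient minimizer of
$E$ built directly from this definition must reproduce the solver's charges.
That characterization — and the minimizer — exists only when the hardness
matrix is positive definite on the conservation plane; the corresponding
tests verify that condition and draw a new parameter set when it fails,
because outside it the stationary point is a saddle and no minimizer exists.

## Two exact invariances, and why one of them matters a lot

Two transformations of a parameter set leave every charge unchanged:

1. **Shift gauge.** Adding a constant $c$ to every $A$ shifts $\bar\chi$ by
   $c$ and moves no charge: only $A$-differences are physically meaningful.
2. **Scale gauge.** Multiplying $A$, $B$ *and* $\kappa$ jointly by $c > 0$
   rescales $\bar\chi$ by $c$ and moves no charge, because the atom rows are
   homogeneous of degree one in $(A, B, \kappa, \bar\chi)$.

The second invariance has a consequence for parameterization that is easy to
miss: *no* procedure whose inputs are molecules and reference charges alone
can identify $\kappa$ or the absolute scale of $(A, B)$, because every
candidate $(\kappa, A, B)$ predicts exactly the same charges as its rescaled
family.  In particular, fitting $(A, B)$ by least squares at each $\kappa$
and scoring candidates by charge quality produces an *exactly flat* objective
in $\kappa$.

The package therefore supports two fitting modes:

* **Anchored** (used whenever every training example carries a reference
  molecular electronegativity $\bar\chi_m$, as the synthetic generator and
  the package's own charge-file format provide): the per-atom regression rows
  $A_{t(i)} + B_{t(i)} q_i + \kappa \sum_j q_j/R_{ij} = \bar\chi_m$ have a
  known right-hand side, which pins both gauges.  $\kappa$, absolute $A$ and
  $B$ are then sharply identified, and on noiseless in-model data the
  parameterization recovers the generating truth to numerical precision.
* **Free** (any $\bar\chi$ reference missing, the situation with real QM
  training data): the $\bar\chi_m$ join the unknowns and are eliminated
  exactly by within-molecule centering.  The remaining rank-1 shift gauge is
  resolved by the minimum-norm solution, and $B$ and $A$-differences are
  recovered per unit of $\kappa$.  The $\kappa$ search is documented to be
  non-informative in this mode; its tie-break returns the smallest grid
  value, and users should treat the resulting set as one representative of
  the scale family.

## Parameterization procedure

`fitLinearForKappa()` solves the linear least-squares problem at fixed
$\kappa$.  Because the regression target is affine in $\kappa$, the
coefficient path is $\beta(\kappa) = u_0 + \kappa u_1$ with $u_0, u_1$
computed once per design from an SVD; rank deficiencies beyond the expected
gauge dimension trigger a warning naming the confounded types.  A type seen
on fewer than `minAtomsPerType` atoms (default 10) is refused outright —
parameters should never be fitted from a handful of atoms.

`searchKappa()` scans a coarse grid (default 0.05 to 1.50 in steps of 0.05,
spanning published EEM values), refits at each $\kappa$, re-solves EEM for
every training molecule and scores the candidate *in charge space* (pooled
$R^2$ by default, pooled RMSD optionally).  Reported quality always comes
from this re-solve, never from the regression residual.  Around the best
grid point it golden-sections the bracket down to `refineTol` (default
$10^{-4}$), then applies a Brent polish inside the final bracket, and — in
anchored mode — also evaluates the closed-form minimizer of the regression
residual $\lVert r_0 + \kappa r_1 \rVert$, keeping whichever candidate scores
best.  The polish steps matter because the fitted parameters inherit the
accuracy of $\hat\kappa$ linearly; a $10^{-4}$ bracket alone would limit
recovered hardness values to roughly $10^{-4}$ accuracy.  Candidates at which
more than 10 % of training molecules are unsolvable are invalidated; a
winning candidate with any $B \le 0$ is rejected as unphysical.  Ties break
toward smaller $\kappa$.

## Quality criteria and aggregation

Quality against reference charges is measured by the squared Pearson
correlation $R^2$, the root mean square deviation, and the mean absolute
error.  The headline numbers pool all atoms of all covered molecules into a
single vector before computing each statistic; per-molecule distributions are
available separately (`perMoleculeQuality()`).  Pooling was chosen because a
parameter set is summarized by one triple of numbers per training or test
set; the alternative (averaging per-molecule statistics) weights small
molecules up and is offered alongside, clearly labelled.  Molecules a set
does not cover are excluded entirely and reported through the coverage
fraction.  $R^2$ against a constant vector is undefined and flagged as such,
never silently set to 0 or 1.

## The synthetic generator

The generator stands in for a curated training database: it emulates the
size range (3–30 atoms) and the atom-type frequency profile of drug-like
training sets (hydrogen most common, then double-bonded and single-bonded
carbon, then oxygen, nitrogen, halogens, sulphur and phosphorus) using the
17 common types and their observed relative frequencies as sampling weights.
Bond orders are assigned so the sampled (element, order) pairs are exactly
reproduced by the typing rules: triple-bonded atoms are chained together,
double-bonded atoms attach to a multiple-bond partner, everything else joins
by single bonds, with occasional ring-closing single bonds added where the
embedded geometry already permits them.  Coordinates come from a stochastic
tree embedding with all pairs at least 1.0 Angstrom apart and bonded pairs
within 1.0–1.8 Angstrom.

What the generator does *not* emulate: chemical valence rules, realistic
bond angles and torsions, protonation states, or formal-charge chemistry
(all generated molecules are neutral by default).  EEM depends on the
geometry only through interatomic distances, the atom types and $Q$, so
plausible distances are the relevant realism target; passing tests therefore
demonstrate the correctness of the machinery on in-model data, not the
chemical quality of any particular parameter set on real molecules.

Reference charges are produced by solving EEM under a sampled ground truth
($A \in (1.5, 4.0)$, $B \in (0.3, 1.6)$, $\kappa \in (0.1, 0.9)$); optional
Gaussian noise is projected back onto the conservation hyperplane (its mean
is subtracted) so that $\sum q = Q$ holds exactly.  One master seed derives
independent per-molecule RNG streams, so enlarging a collection never
changes the molecules already generated.  Random hardness/screening
combinations near the singular manifold can produce large charge magnitudes;
such systems are legal inputs (the condition guard refuses only estimates
beyond $10^{10}$), and the occasional molecule whose ground-truth system is
refused is regenerated deterministically from the next attempt of its own
stream.

## Numerical choices

* Dense LU solve with partial pivoting for the $(N+1)$-system; molecules
  here are at most a few hundred atoms, so sparse machinery is unwarranted.
* Condition estimate guard at $10^{10}$: beyond it the solver refuses rather
  than return garbage, naming the molecule.
* Distance guard: any interatomic distance below 0.5 Angstrom (configurable)
  is degenerate geometry and is refused with the atom pair named.
* Specific type keys ("C2") always beat bare-element wildcard entries ("C",
  used by legacy parameter sets covering all bond orders).
* Isolated atoms type as order 1: an unbonded atom has no multiple bond.
* SDF coordinates are written with 4 decimals (the format's field width);
  parameter files carry 17 significant digits so write–read cycles are
  lossless; charge files carry 9 decimals.
* Recovery and validation experiments in the test suite use 300 training
  molecules with 8 common atom types (about 5,000 atoms), 1,000 molecules
  for conservation sweeps, and 50 molecules for the energy-minimizer
  cross-check; these sizes give stable statistics while keeping the suite
  quick to run.

## Known limitations

* $\kappa$ and the absolute $(A, B)$ scale are not identifiable from
  charges alone (scale gauge); anchoring requires reference molecular
  electronegativities, which standard QM charge sets do not provide.
* Bond-order typing relies entirely on the input's bond block; Kekulé
  single bonds in rings are not promoted to aromatic, so the same ring can
  type differently depending on how the file encodes it.
* The generator's geometric plausibility is deliberately not chemical
  validity; fitted parameter quality on real molecules depends on real
  reference charges, which are out of scope here.
* V3000 SDF records, fragment charge constraints, periodic systems and the
  QEq/SQE model variants are not supported.
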