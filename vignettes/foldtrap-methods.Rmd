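---
title: "Models and methods in foldtrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in foldtrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(foldtrap)
```

foldtrap implements the computational pipeline around a simple biological
observation: in quantitative refolding experiments a subpopulation of
soluble protein stays misfolded for days or longer, even in the presence
of ATP-driven chaperones, and it can do so because its structure is nearly
native. This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the package's synthetic-data
tests can show.

## Two-pathway refolding kinetics

The probability of being non-native after a dilution jump is modelled as

$$P_{NN}(t) = a_0 e^{-k_1 t} + a_1 e^{-k_2 t}, \qquad a_0 + a_1 = 1,$$

two parallel folding pathways with no interconversion: a fast phase
(amplitude $a_0$, rate $k_1$, per minute) and a slow, misfolded phase
($a_1$, $k_2$). `fit_biexponential()` imposes the amplitude constraint by
substitution (it is exact, not penalized), optimizes rates as $\log_{10}k$
inside box bounds $[-30, 2]$ — wide enough for slow rates around
$10^{-23}$ per minute without underflow — from a multi-start grid ($k_1$
from the first e-fold crossing time, $k_2$ from
$\{10^{-m}/\mathrm{duration}\}_{m=0..6}$), and finishes with a
Levenberg–Marquardt polish. On noise-free model data the parameters are
recovered to machine precision.

**Measurability.** When $k_2 t \ll 1$ over the whole course, the slow term
is effectively a plateau plus an invisible linear decrease; only the
plateau $a_1$ is identifiable. The package's rule of thumb is that a decay
time up to ten times the course duration can still be resolved, so
`measurability_limit(duration)` returns $1/(10\times\mathrm{duration})$
and any fitted $k_2$ below it is flagged `lower-bound-only`. The flag is a
reporting contract on the *fitted* value: with a small slow amplitude,
1% noise can push the fitted slope of a truly static plateau slightly
above the limit, which is why the package never interprets a flagged rate
as precise and why time constants are also reported as orders of
magnitude (`time_constant_order()`, $10^{\mathrm{round}(\log_{10} 1/k_2)}$
minutes). `minutes_to_years()` is a plain unit conversion (525,960 minutes
per year); conversions quoted elsewhere that disagree with it are not
reproduced.

**Uncertainty on the slow rate.** Published courses often lack error bars;
the package follows the convention of assuming 1% uncertainties when none
are reported. `k2_bounds()` refits the model to the data shifted up and
down by one uncertainty and returns the extreme slow rates of the two
envelope fits. This envelope refit is an interpretation — the propagation
method behind published bound pairs is not specified — and it collapses to
zero width at zero uncertainty, which the tests assert.

**Model selection.** The diagnostic for needing two exponentials is
structure in the residuals of a single-exponential fit.
`runs_test_residuals()` is a Wald–Wolfowitz runs test, one-sided against
*too few* runs: systematic misfit clusters residual signs, whereas an
excess of runs carries no evidence of misfit in this setting (the
perfectly alternating pattern must read as random-consistent).

## The single-ring GroEL/GroES cycle

The ATP-depletion question — could the trapped fraction simply reflect
chaperones running out of ATP? — is answered with an 11-species
mass-action network: free GroEL loads seven ATP (treated as one bundle
species), captures unfolded client, is capped by GroES, hydrolyses,
and releases client, GroES, and ADP; release partitions the client into
folded ($\varphi_F$), misfolded ($\varphi_M$), or still-unfolded
($1-\varphi_F-\varphi_M$) fractions. Free unfolded client also folds
spontaneously at $k_6$ with its own bulk partition pair. A basal cycle
($k_7$, $k_8$) hydrolyses GroEL-bound ATP without client.

Two structural points deserve note. First, the basal branch is implemented
as G·7ATP $\to$ G·7ADP $\to$ G (unimolecular in the bound complex), which
is the only reading under which GroEL mass is conserved and which matches
the appearance of the linear $+k_8[\mathrm{G|7ADP}]$ term in the free-GroEL
equation. Second, client mass is conserved exactly when the bulk pair sums
to one (a spontaneous folding event always resolves to folded or
misfolded); `partition_coefficients()` warns otherwise. Integration uses
lsoda with relative tolerance $10^{-8}$ and absolute tolerance $10^{-10}$
µM (both exposed), and the tests require the three conservation laws to
hold to $10^{-6}$ relative across random parameterizations.

**Fitting the partition coefficients.** $\varphi_F$ is scanned over
0.001–1.001 in steps of 0.001 (the odd endpoint is kept deliberately;
the simplex constraint removes infeasible values anyway), with
$\varphi_M = P_{NN}^{eq}/(1-P_{NN}^{eq})\cdot\varphi_F$ tied to the
experimental plateau, taken from the final time point by default (a
two-point mean is an option). Candidates are ranked by Pearson $R^2$ with
total absolute error as the tie-break; because $R^2$ is nearly flat in
$\varphi_F$ on well-fitting data, candidates within $10^{-6}$ of the
maximum are treated as tied — without this, numerical noise in the
correlation picks an arbitrary member of the plateau and recovery to grid
resolution fails. Self-consistency recovery (plant $\varphi_F$, refit) is
exact to the grid when the bulk channel is off; with an active bulk
channel the plateau ratio no longer equals $\varphi_M/\varphi_F$ and the
scan family need not contain the planted pair.

**ATP accounting.** The state stores bundle concentrations, so reported
consumption multiplies by 7 (`atp_accounting = "bundle7"`); the literal
bundle count is available because published usage figures do not state
which convention they use. Representative experiment configurations with
initial ATP at or above 1000 µM consume well under 300 µM over their
courses, leaving a large free-ATP pool — the package's restatement of the
depletion argument.

## Dissociation constants from occupancy

For one chaperone and one client in a simulation volume $V$ (in Å$^3$),
the unbound probabilities equal $1 - p$ with $p$ the bound fraction, and

$$K_D = \frac{(1-p)^2}{p}\cdot\frac{1}{V}\cdot
\frac{1}{6.022\times10^{23}\times10^{-27}}\ \mathrm{mol/L}.$$

The single-copy identity $P_{\mathrm{chaperone}} = P_{\mathrm{client}} =
1-p$ is forced by the simulation setup and made explicit here. Default
volumes are spheres of radius 160 Å (GroEL) and 200 Å (DnaK/HtpG). Frames
are classified bound when the intermolecular contact count reaches a
threshold; thresholds are always recorded inputs, with a two-means split
of the contact histogram as the default when none is given. On
well-separated two-state data the estimate moves by less than 5% across
thresholds spanning the inter-mode gap. Bound fractions of exactly 0 or 1
are censored (no number is invented for a trajectory that never unbinds).
Replicate estimates get t-based 95% confidence intervals; odds ratios
(attractions on/off, unfolded or misfolded vs folded) carry a two-tailed
t-test across replicate log-ratios, and group comparisons use a two-tailed
permutation test on the difference of means with exact enumeration when
feasible and ties counted as extreme.

## Coarse-grained energetics

`cg_energy()` evaluates the six-term Cα potential — harmonic virtual
bonds, four-term cosine torsions, a double-well (log-sum-exp) bond-angle
potential, Debye–Hückel electrostatics (Debye length 10 Å, dielectric
78.5, charges $+e$ for Lys/Arg and $-e$ for Asp/Glu), a 12-10-6 native
contact term, and the same form with a tiny well depth (0.000132
kcal/mol) for non-native pairs — as a static scorer; there is no
integrator. Two conventions are exposed rather than guessed: the nonbonded
exclusion window (`nb_min_sep`, default 4) and the per-contact well depths
and diameters, loaded from a parameter file. One algebraic fact the tests
pin down: the $13x^{12}-18x^{10}+4x^6$ form has its global minimum exactly
at $r = \sigma$ (depth $-\epsilon$) with a positive desolvation barrier
near $1.45\sigma$; since $\sigma$ is the native distance divided by
$2^{1/6}$, the well bottom sits slightly inside the native distance.

## Entanglement topology

A non-covalent lasso is a backbone loop closed by a native contact
$(i,j)$, threaded by an N- or C-terminal tail. The package computes the
Gauss linking number of the contact-closed loop (closure segment included)
against each tail by the midpoint discretization of the Gauss double
integral, rounds half-away-from-zero, and keeps per-tail partial values.
Tails exclude the five residues adjacent to each loop terminus to suppress
spurious near-loop contributions (exposed as `tail_excl`). The tests
verify the discretization against an independent, exact segment-pair
solid-angle evaluation and against the closed form for a circle and an
axial segment.

The entanglement-change metric is

$$G = \frac{1}{N}\sum_{(i,j)}\Theta\big((i,j)\in nc \,\cap\,
g(i,j)\neq g^{\mathrm{native}}(i,j)\big),$$

the fraction of native contacts, formed in the current structure, whose
rounded total linking number differs from the native reference. Crossing
residues are localized as the tail segments with the dominant per-segment
Gauss contribution (one per unit of linking, kept at least two segments
apart) — an approximation standing in for surface-triangulation piercing
detection, adequate on the package's fixtures. For a lost entanglement the
native structure supplies the crossings; for a gained one, the current
frame. Degenerate changes are clustered on six discrete descriptors
(crossing counts, rounded partials, and change types per tail) with all
crossing residues within ±5, and each cluster is represented by its
minimal loop (ties to the smaller start index). The change-type labels
{gain, loss, switch} compare magnitudes and signs of the rounded partials
and are an interpretation of a taxonomy defined elsewhere.

Contact-map defaults (8 Å Cα cutoff, $|i-j|\ge 4$, formed tolerance 1.2×
native distance) are stated, not derived, and all are configuration keys;
a secondary-structure restriction is honoured through a user-supplied
mask rather than an embedded assigner. Windowed-mode Q uses bins of width
$1/N_{\mathrm{contacts}}$ (each formable-contact count is a bin) and
stride one; a trajectory is long-lived misfolded when no window mode
reaches the native-ensemble reference. Solvent accessibility is
Shrake–Rupley with golden-spiral sampling (960 points by default, within
1% of the single-sphere closed form), and exposure changes around a cut
site average the ±5-residue window by default.

## LiP-MS consistency and its permutation null

Predicted entanglements and significant half-tryptic peptides are
compared through two binary matrices over entanglements × peptides:
overlap $O_{e,l}$ (positive Jaccard index between the residues within
±5 of the proteinase-K cut site and those within 8 Å of the
entanglement's crossing residues, distances taken on an explicitly chosen
structure) and sign agreement $S_{e,l}$ (simulated exposure change at the
cut site and experimental $\log_2 R/N$ share a sign; a zero on either
side agrees with nothing, and $S$ is gated by $O$). Per-timepoint means
give the statistics $\langle O\rangle_t, \langle S\rangle_t$.

The null distribution redraws cut sites from a theoretical half-tryptic
distribution: intrinsic per-type cut propensities
$P_{\mathrm{observed}}/P_{\mathrm{proteome}}$ (scaled to valid acceptance
probabilities) combined with an optional peptide length / internal
trypsin-site probability table, sampled by the two-uniform rejection rule
into a unique site set. Observed ratio signs are kept and paired with the
drawn sites — the permutation moves positions, not effect directions. One
shared site set per permutation serves all timepoints (truncated to each
timepoint's observed count); independent per-timepoint redraws are
available as an option. A permutation counts as at least as consistent as
the data when both statistics are exceeded at two or more timepoints, one
of them the longest; the p-value is the plain exceedance fraction.

**Tie handling is the load-bearing choice.** The statistics are discrete
with large atoms. If ties are excluded (strict inequality), almost no
permutation dominates almost any observed vector, p-values are generically
tiny, and the test rejects about half of *null* datasets at the 0.05
level — we verified this on datasets whose observed and permuted
statistics are exchangeable by construction. Counting ties as exceedance
restores calibration (measured rejection ≈ 0.05 under the pure-noise null
with shared draws) at the cost of some power. The default is therefore
`ties = "count"`; `ties = "strict"` reproduces the literal rule for
comparison. Even with ties counted, the multi-coordinate AND-rule is not
a rank statistic, and its calibration degrades when the data contain
positional clustering of cut sites that the type-based theoretical
distribution cannot represent (measured rejection 0.10–0.2 when null
datasets carry accessibility clustering at random locations). This is a
genuine limitation of the method, not of the implementation.

## The synthetic-data generators and what passing tests show

Every stage is tested against generators with known ground truth; their
defaults are the package's study conditions.

- **Time courses**: even grids over 30–600 minutes (the range of the
  refolding literature), additive Gaussian noise with sd 0.01 in
  probability units (the 1%-uncertainty convention), clipped to [0, 1].
- **Contact trajectories**: a two-state Markov chain with the stationary
  bound probability and mean bound dwell as parameters; contact counts are
  Poisson around per-state means (50 bound / 3 unbound by default). The
  within-state count distribution is a stand-in — no distributional claim
  about real trajectories is made, only two-state occupancy structure.
- **Toy lassos**: a planar bead circle closed by its first/last contact,
  with the C-tail routed outside the loop and then straight along (or
  beside) the loop axis; the threaded geometry has provable |link| = 1,
  sign set by mirroring, verified against the exact segment-pair oracle.
- **LiP-MS tables**: random sequences, unique cut sites drawn per residue
  type propensity, half-tryptic spans to the nearest downstream trypsin
  site, standard-normal background ratios. A planted effect multiplies
  local cut propensity by 8 within ±5 residues and fixes the ratio sign —
  reflecting that a conformational change both raises local proteinase-K
  accessibility and sets the direction of the abundance change. The
  calibration/power fixture is a 162-residue lasso chain (15 Å loop, 30
  beads, 300 Å thread; one gained crossing), an exposure-change field of
  N(0, 3 Å²) noise with a −20 Å² burial at the crossing, 15 cut sites per
  timepoint and 3 timepoints; the calibration null has no effect sites.

Synthetic data emulate noise, two-state switching, loop threading, and
cut-site sampling — not real structural ensembles, digitization error,
correlated measurement noise, or proteome-wide coverage bias. Passing
tests demonstrate that the algorithms compute what they claim under known
truth; they do not validate the biological models on real data.

## Numerical choices at a glance

- Rates in $\log_{10}$ with box bounds [−30, 2]; amplitude constraint by
  substitution; LM polish after multistart.
- lsoda, rtol $10^{-8}$ / atol $10^{-10}$ µM; negative excursions within
  tolerance clipped to zero.
- Linking numbers: midpoint Gauss discretization; rounding
  half-away-from-zero before every equality comparison; rigid-motion
  invariance to $10^{-9}$.
- $\varphi$ scan: $R^2$ ties at $10^{-6}$ broken by absolute error.
- Permutation test: 1000+ permutations, shared draws, ties counted; no
  continuity correction.
- Problem sizes in the shipped checks: 100 recovery fits, 50 network
  parameterizations, 20 $\varphi$ draws, 1000 null and 100 planted LiP-MS
  datasets at 1000 permutations each.

## Known limitations

- Crossing localization by dominant Gauss contribution can mis-rank
  crossings on contorted tails; the fixtures it is validated on are
  well-separated.
- The φ grid scan re-integrates the network per candidate; for very long
  time courses, thin the requested grid or relax the scan tolerances.
- The LiP-MS permutation rule is anti-conservative under strict tie
  handling and under positional cut-site clustering (see above).
- Kinetic fits assume no reverse transitions (no unfolding of F or M) and
  shared rate constants across proteins when applied as given here.
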