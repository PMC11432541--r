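---
title: "Methods: the strings-and-binders chromatin model in sbsfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the strings-and-binders chromatin model in sbsfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`sbsfold` implements a strings-and-binders (SBS) picture of chromatin
folding. A chromosomal segment is a coarse-grained bead-spring chain; each
bead may expose one or more *binding-site types*, and for every type a
population of spherical *binders* diffuses in the simulation box. A binder
attracts only beads that carry its cognate type. Because one binder can
touch two or more beads at once, binding mediates effective bead-bead
bridging, and above threshold concentrations/affinities the chain switches
from a self-avoiding coil to a compact, phase-separated globule. With
several types arranged in overlapping domains along the chain, the collapse
becomes a micro-phase separation that reproduces TAD-like contact
structure.

The force field is the classic Kremer-Grest setup plus the binder
attraction:

* **FENE bonds** between consecutive beads,
  $U = -\tfrac12 K R_0^2 \ln[1-(r/R_0)^2]$ with $R_0 = 1.6\,\sigma$ and
  $K = 30\,k_BT/\sigma^2$;
* **WCA excluded volume** between *all* particle pairs (beads and
  binders): Lennard-Jones truncated at $2^{1/6}\sigma$ and shifted to zero
  there. Applying WCA to bonded pairs too gives the standard equilibrium
  bond length $\approx 0.97\,\sigma$;
* **cognate attraction**: a truncated-shifted Lennard-Jones acting only
  between a binder and the beads carrying its type, cut at $1.5\,\sigma$.
  The affinity parameter $E_{bb}$ (in $k_BT$) enters as the Lennard-Jones
  depth parameter $\varepsilon$; after truncation and shifting the actual
  well depth is $\approx 0.68\,E_{bb}$. We use the plain
  $\varepsilon = E_{bb}$ convention throughout and state affinities in
  those units.

Dynamics follow the underdamped Langevin equation at friction
$\zeta = 0.5$ and temperature $T = 1$ ($m = \sigma = k_B = 1$), integrated
with velocity-Verlet at $\Delta t = 0.012$ model-time units; friction and
Gaussian noise of per-component variance $2\zeta m k_B T/\Delta t$ enter
the force evaluation once per step. The box is cubic and periodic.
Positions are integrated unwrapped so that all analyses see whole
molecules; forces use the minimum-image convention. Setting the friction
to zero turns the integrator into plain NVE, which the test suite uses to
check energy conservation. Neighbour search uses cell-sorted Verlet pair
lists with a $0.5\,\sigma$ skin, rebuilt when any particle has moved more
than half the skin; the engine guarantees bit-identical forces to the
brute-force all-pairs evaluation, which is kept as a reference path.

## Initial states and the observable

Runs start from an open self-avoiding walk grown with backtracking (bond
lengths in $[0.95, 1.05]\,\sigma$, all non-bonded pairs at least
$0.9\,\sigma$ apart). Binders are injected uniformly at random with the
same minimum separation. The folding order parameter is the bead gyration
radius $R_g(t)$; its time track drops sharply at the coil-globule
transition and then plateaus. `detect_collapse()` summarises a track by
the coil level (mean of the first 5% of samples), the plateau level (mean
of the last 25%) and the first crossing of their midpoint; a relative drop
below 10% counts as "no collapse".

## Choice of the production point

The coil-globule transition needs binder concentration *and* affinity
above their thresholds, but in a particle-based implementation the
concentration axis is bounded above as well: binders condense onto the
chain, and once the bound-binder load is large the polymer-binder
co-condensate is as large as the coil itself, so no $R_g$ collapse is
observable. Direct sweeps with this engine (homopolymer, $N = 200$,
$L = 20\,\sigma$, $E_{bb} = 5$) show clean collapse for total volume
fractions around $c \approx 0.005$-$0.01$ and loss of the transition for
$c \gtrsim 0.02$. The package therefore fixes its production point at
$c = 0.01$ (split equally across types) and $E_{bb} = 5\,k_BT$ - safely
inside the phase-separated region while keeping the condensate small
relative to the chain. The defaults are exposed in the presets and config
and can be changed freely.

## The synthetic binding profiles

Real inferred chromatin profiles are not shipped with the package;
`make_binding_profile()` emulates their statistical structure: contiguous
binding-site domains tile the chain (geometric length distribution),
overlay domains create beads carrying several types, and a fraction of
beads stays inert. The parameters are the number of types and domains, the
mean domain length, the target fraction of multi-label beads
(`overlap_prob`) and the inert fraction. The overlapping, combinatorial
arrangement is not cosmetic: overlap is what couples the type-specific
globules to each other, and profiles with negligible overlap collapse into
strings of disconnected blobs rather than a single condensed structure.

What the generator does *not* emulate: binding-energy heterogeneity
between sites of one type, sequence-correlated domain placement, and any
relation between domain boundaries and real genomic annotations. Passing
tests on these synthetic profiles therefore demonstrates correctness of
the machinery and the qualitative physics, not agreement with any
particular locus.

## The desk ensemble

All quantitative ensemble checks run on a scaled-down "desk" preset chosen
to finish on one CPU in minutes: $N = 200$ beads, 4 types
(`overlap_prob = 0.55`, 10% inert, profile seed fixed), box
$L = 20\,\sigma$, $c = 0.01$, $E_{bb} = 5$, $3\times10^5$ steps per
replicate and 50 independent replicates (fresh coil, fresh binders, fresh
noise each). The full-scale preset (`paper_preset()`: $N = 800$, ten
types, $L = 50\,\sigma$, $10^8$ equilibration steps, up to 300 replicates)
is provided but takes hours per replicate; the desk ensemble reproduces
its phenomenology - collapse to a prolate, partially ordered globule -
at reduced size. Two systematic differences of the scaled ensemble are
worth keeping in mind when comparing with full-scale numbers: with only
4 types and 200 beads the condensate cross-section stays slightly
triaxial (the middle-to-short semi-axis ratio b/c sits near 1.2 rather
than 1.0), the $R_g$ drop through the transition is ~45-50% rather
than ~70% (a 200-bead coil is proportionally less expanded than an
800-bead one), and the folding degeneracy is smaller, so independently
collapsed molecules correlate more strongly (pairwise distance-map $r'$
means around 0.3 rather than ~0.1).

## Ensemble analyses

Contact maps mark bead pairs closer than a threshold (strict `<`,
diagonal fixed at 1 and excluded from statistics). The default threshold
is $3.5\,\sigma$, the midpoint of the commonly used 2-5 sigma range; all
map routines accept the whole range. Ensemble maps are entrywise means of
single-molecule binary maps; `bin_matrix()` performs block-mean binning
(e.g. 800 beads at 2.5 kb to 80 bins of 25 kb) and `contact_probability()`
averages entries at fixed genomic separation.

Three similarity statistics compare maps: the Pearson correlation over
upper-triangle entries; the *genomic-distance corrected* Pearson $r'$, in
which each matrix is first residualised by the mean of its own entries at
every separation $|i-j|$ (each matrix supplies its own expected-by-distance
profile - the residual correlation then ignores the trivial proximity
signal, and a randomly folded control chain scores near zero against any
structured map); and the Spearman correlation (mean ranks on ties).
Degenerate inputs - zero variance, or matrices that are pure functions of
$|i-j|$, whose residuals vanish - return `NA` flagged `undefined` rather
than a silent zero. Masked (NA) bins are dropped pairwise.

## Single-molecule analyses

Distance maps are plain Euclidean pairwise distances of unwrapped bead
coordinates. Structural heterogeneity across an ensemble is quantified by
the distribution of pairwise $r'$ between single-molecule distance maps -
the same residualisation as for contact maps, applied per molecule.

Shape is described by two second-moment tensors, both computed about the
centre of mass (the inertia tensor is centred even though its textbook
definition is origin-dependent; any other choice would make the result
depend on the arbitrary box origin):

* the **inertia tensor** (unit masses), whose sorted principal moments
  $I_a \le I_b \le I_c$ invert to the semi-axes of the equivalent uniform
  ellipsoid, $a^2 = \tfrac{5}{2N}(I_b + I_c - I_a)$ and cyclic; the
  smallest moment maps to the longest axis so $a \ge b \ge c$ by
  construction. Negative radicands (degenerate, e.g. collinear clouds) are
  clipped to zero and flagged, and flagged molecules are excluded from
  ensemble summaries with their count reported;
* the **gyration tensor**, eigenvalues sorted descending, giving the
  ellipticity $\epsilon = 2\lambda_3/(\lambda_1+\lambda_2)$ ($=1$ for a
  sphere) and $R_g^2 = \lambda_1+\lambda_2+\lambda_3$.

Volumes use $V = \tfrac43\pi abc$ and $V = \tfrac43\pi R_g^3$; ensemble
volumes are means of per-molecule volumes, not volumes of mean
descriptors, so that the convexity gap between $\langle R_g^3\rangle$ and
$\langle R_g\rangle^3$ is retained.

The prolate-versus-spherical comparison of the axis-ratio distributions
uses a Mann-Whitney test with $U = \sum [x_i > y_j] + \tfrac12[x_i=y_j]$.
For $nm \le 400$ the two-sided p-value is exact, from the full
permutation distribution of $U$ given the pooled (possibly tied) values,
computed by dynamic programming over twice-ranks; larger samples use the
normal approximation with tie-corrected variance and continuity
correction.

## Phase-diagram sweeps

`run_sweep()` scans a grid of (concentration, affinity) points with
replicates and per-point deterministic seeds and summarises each by its
plateau $R_g$. `estimate_threshold()` places the transition where the
interpolated curve crosses the midpoint between the coil plateau (low
side) and globule plateau (high side); interpolation is linear in
log-parameter when the grid is positive (so a hard step between two grid
points reports their geometric mean), linear otherwise. Concentration
grids are logarithmic; affinity grids linear from 0 to 8 $k_BT$. The
default sweep subject is the homopolymer, and the affinity sweep is run
at fixed $c = 0.01$, the package's production concentration; sweep grids
should stay in the dilute-binder regime discussed above, where plateau
$R_g$ responds monotonically to both control parameters. Two caveats for
scaled-down sweeps: at run lengths of order $10^5$ steps the strongest
couplings (above roughly 5 $k_BT$) kinetically arrest in partially
coarsened states whose $R_g$ is not an equilibrium plateau, and threshold
positions are naturally quoted on the realized well-depth scale
($0.68\,\varepsilon$ for the truncated-shifted attraction), the
physically meaningful binding affinity.

## Unit calibration

Model units map to physical units in two independent ways: genomically,
$\sigma = (s/G)^{1/3} D$ with $s$ the genomic content per bead, $G$ the
genome size and $D$ the nucleus diameter (the bead occupies the volume
fraction $s/G$ of the nucleus - note the cube root applies to the ratio,
which is the only dimensionally consistent reading); and by imaging,
$\sigma = R_g^{\mathrm{imaging}}/R_g^{\mathrm{model}}$. The reference
$\sigma$ is the arithmetic mean of the two. Time maps through the
Brownian time of a sphere of diameter $\sigma$,
$\tau = 6\pi\eta\sigma^3/(k_BT)$, with default viscosity
$\eta = 0.01$ Pa s and $T = 300$ K; defaults put $\tau$ in the
millisecond range. Conversion helpers report lengths in nm and volumes in
$\mu m^3$ (one decimal for $\sigma$, two for volumes, matching the
precision such quantities are usually quoted at).

## Numerical choices and degenerate inputs

* Timestep 0.012 with FENE/WCA is the standard stable choice; the FENE
  bound $r < R_0$ is monitored every force evaluation and a violation
  aborts the run with the last stable sample.
* The engine RNG is xoshiro256++ with a ziggurat normal sampler, seeded
  from the user-facing integer seed; it is independent of R's RNG, so
  package-level analyses can use R's generator without perturbing
  trajectories. All ensemble and sweep seeds derive deterministically
  from one master seed and stay below $2^{31}$.
* Correlation routines flag degeneracy instead of returning 0;
  `heterogeneity()` excludes degenerate maps and reports how many.
* `estimate_threshold()` refuses curves whose total drop is below 10%.
* Collinear or coincident bead clouds flag the inertia inversion as
  degenerate; sweeps flag failed replicates and keep the rest.

## Problem sizes used by the tests

The suite runs entirely on synthetic data generated at test time: the
desk ensemble above (50 replicates, about 20 s each), a homopolymer
affinity sweep at $N = 100$, $L = 15\,\sigma$, $c = 0.01$ with short
(1e5-step) runs, self-avoiding-walk ensembles up to $N = 320$, and
$10^5$-point ellipsoid clouds for the shape oracles. These sizes were
chosen so that each check is statistically meaningful for its stated
tolerance while the whole suite stays in the tens of minutes on one core.

## Known limitations

* Binder-binder interactions are purely repulsive; cooperative binder
  oligomerisation is outside the model.
* No hydrodynamics; the Langevin friction sets a single diffusive scale.
* The scaled desk ensemble is not fully equilibrated in the
  thermodynamic sense (full-scale equilibration uses $10^8$ steps);
  residual prolateness of its globules is part of the reported numbers,
  and is consistent with the prolate single-molecule shapes seen at full
  scale.
* At most 30 binding-site types (bitmask encoding).
* Contact-map comparison assumes equal binning on both sides; balancing
  or normalisation of experimental matrices is out of scope.
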