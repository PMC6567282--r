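---
title: "Stability and shape of DNA-linked nanoparticle diamond lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability and shape of DNA-linked nanoparticle diamond lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdlattice)
```

## The system and the model

`cdlattice` models superlattices with cubic-diamond (CD) symmetry
assembled from two building blocks: a DNA-origami *tetrahedral cage*
whose four truncated vertices carry single-stranded sticky ends, and an
isotropically DNA-functionalized *nanoparticle* (NP). The cage provides
the 4-valent directional bonding a diamond lattice needs; the NP
hybridizes to it through complementary sticky ends. The CD lattice is
two interpenetrating FCC sublattices (NPs and cages) offset by a quarter
body diagonal; every cage has four tetrahedrally arranged NP neighbours.

All quantities are in reduced Lennard-Jones units: lengths in sigma
(about 0.65 nm), energies in the pair energy eps, temperature in eps/kB
(kB = 1), all site masses 1. Lattice runs use T = 0.09, below the
sticky-end melting temperature.

### Coarse-grained topology

* **Cage** (`build_cage()`): six edges of seven beads (diameter 9.9),
  truncated vertices of three beads each (the terminal beads of the
  edges meeting there), a 40-sigma central site, and four grafted
  strands whose first nucleotide (the anchor) is tethered to the center
  by a stiff FENE bond. Edges carry first- and second-neighbour FENE
  bonds (the second-neighbour rest length enforces linearity, so no
  angle terms are needed on edges). All parameterised bonds are built
  at their tabulated rest lengths; this closes the geometry and fixes
  the cage circumradius at about 58.9 sigma (edge about 96 sigma). The
  anchor-to-truncation-bead tethers have no tabulated row and take
  their rest length from the constructed geometry. A consequence of the
  tabulated anchor-to-center rest length (37.48) is that the anchor
  sits *inside* the truncation face (at radius ~51): the strand threads
  outward through the gap between truncation beads. The vertex bead
  pattern is otherwise underdetermined, and this is the placement
  consistent with every tabulated bond length simultaneously.
* **Nanoparticle** (`build_np()`): 20 vertex sites (diameter 1) on a
  regular dodecahedron of circumscribed diameter d in [40, 120], one
  central site, stiff FENE bonds vertex-vertex and center-vertex, and
  20 radially grafted strands. The built edge length is the exact
  d / (sqrt(3) phi) = d/2.8025; the bond rest lengths use the tabulated
  rounding l = d/2.8 (a 0.9 percent strain, far inside the FENE range).
  The central site's nominal diameter is d, but its excluded-volume
  range is the inscribed sphere (pair diameter 0.7947 d), so the vertex
  sites and grafts protrude while strands cannot enter the body.
* **DNA** (two sites per nucleotide): 15 nucleotides per strand, seven
  inert spacers (base letter N, no complement anywhere) then eight
  sticky bases written outward. Cage strands carry `GCGCAGTC`, NPs its
  reverse complement, so full pairing exists only between a cage and an
  NP and neither 8-mer is self-complementary. Backbone bending angles
  V = ka (1 + cos theta) along the strand and at the graft carry the
  DNA stiffness ka in [0.5, 2], the experimental proxy for salt
  concentration (one shared knob for strand and graft stiffness).

### Potentials

Bonds use the shifted FENE form with maximum extension R0 beyond the
shift Delta; the embedded truncated LJ core puts the standard
(Delta = 0) minimum at 0.9609, printed as 0.96 throughout the parameter
tables (`fene_rest_length()` returns the exact value). Non-bonded pairs
repel through the expanded WCA potential, whose core is displaced by
Delta_ij = (d_i + d_j)/2 - 2^(1/6) so that repulsion begins at the sum
of radii for any size pair; it is cut and shifted to zero at
Delta_ij + 2^(1/6). Bonded pairs carry no pair term (the 7.32 edge-bead
spacing deliberately overlaps the 9.9 bead diameter), and the cage
central site is excluded from its own frame beads: it exists to keep
strands out of the body, and the mid-edge beads sit inside its
exclusion zone by construction.

The only attraction is between complementary bases (A-T, C-G) of
distinct strands: an unshifted 12-6 well with sigma_bp = 2^(-1/6)
(minimum at base contact, 1 sigma), cutoff 2.5, and depth
`default_base_pair_epsilon()` = 0.55. The well depth is the package's
own calibrated parameter: it is set by the two-strand melting scan
(`build_strand_pair()` plus `count_base_pairs()`): at 0.55 the 8-mer
pair is hybridized essentially always at T = 0.09 and never at
T = 0.30, placing the melting midpoint between the lattice working
temperature and the hot control, which is the only property the
analysis relies on.

### Dynamics

`run_nvt()` integrates velocity Verlet with either a Nose-Hoover
thermostat (damping 1.0, the lattice default) or a Langevin thermostat
(robust for very small systems); `run_npt_zero_pressure()` adds an
isotropic Berendsen-style cell rescale (damping 3.0) driving the virial
pressure to zero while preserving the triclinic angles. This barostat
is a deliberate simplification of a full extended-Lagrangian NPT: the
zero-pressure runs are used to relax the lattice constant to its
stress-free value, not to sample cell fluctuations. The timestep is
0.003. Fully bonded lattices come from the two-step protocol
(`prepare_bonded_lattice()`): anneal one tethered primitive cell until
all four cage strands are hybridized, then replicate unwrapped, remove
the tethers, and relax at P = 0.

The default lattice constant places the two straight strands of each
link side by side with their sticky regions in register (eight paired
bases span seven backbone gaps), with the NP strand laterally offset
through the gap between the cage's truncation beads. The rest-geometry
scale is used as-is (not pre-shrunk) because any shrink factor throws
the pre-hybridized registers off by whole bases; the barostat then
relaxes b.

## Synthetic data: what the surrogate emulates

The analysis stages assume Gaussian lattice vibrations with no
diffusion. `sample_correlated_modes()` draws exactly that: normal-mode
amplitudes of the harmonic lattice model with variance kB T / omega^2,
back-transformed to real-space displacements, giving displacement
covariances kB T D(q)^-1 by construction. Frames are i.i.d. by default
because every downstream estimator uses equal-time covariances only; an
Ornstein-Uhlenbeck mode exists to exercise plateau detection on
time-lag curves. `sample_independent_oscillators()` and
`sample_rigid_body_rotations()` realise the independent-oscillator
picture with per-species translational and rotational stiffness,
including the shared-arc-length mode where `<phi^2> = (2 s / d)^2` per
species. `perturbed_ideal_lattice()` provides Debye-Waller-style
disorder for structure-factor fixtures. What the surrogates do *not*
contain: anharmonicity, defects, melting, and the collective surface
processes discussed below — so surrogate-based tests validate the
estimators, not the bead-level model.

The end-to-end study (`run_study()`) maps (d, ka) to generator
parameters once, chosen to match the amplitude behaviour the full
simulations exhibit: `<u^2>` grows roughly like sqrt(d) (about a
doubling across d = 40-120) and shrinks as 1/ka; the shared arc grows
weakly (s ~ d^0.15), so the NP orientation amplitude falls steeply
(~d^-1.7) while the cage amplitude grows modestly (~d^0.3); the angular
lattice stiffness tracks the NP rotational locking (ktheta ~ d^2).
Under these conditions the relative free energy rises with both NP size
and DNA stiffness, with the NP rotational term dominant — the
qualitative structure of the full calculation.

## Surface energies and crystallite shape

`broken_bond_density()` counts severed nearest-neighbour links per unit
area exactly, on a periodic supercell, for any low-index cut plane and
termination. The minimal terminations give 2 broken bonds per surface
body on (100), 1 on (110) and 1 on (111) (3 for the unfavourable (111)
termination), and per-area ratios gamma100:gamma110:gamma111 =
sqrt(3) : sqrt(6)/2 : 1 = 1.7321 : 1.2247 : 1, independent of supercell
size. `surface_energy_from_slab()` implements the excess-energy
estimator gamma = (E_slab - E_bulk_matched) / (2A) with the bulk
reference scaled per body to the slab's composition (the (111) and
(110) slab faces differ in species) and block-averaged uncertainties.

`wulff_construct()` builds the equilibrium crystallite as the
intersection of half-spaces at distances proportional to the facet
energies, expanded over the full cubic point group (48 operations), and
reports per-family facet area fractions, a shape label, and the
constancy of gamma/ell across retained facets (machine precision by
construction; verified from the vertex geometry). Facets below an area
fraction of 1e-6 are treated as absent; the threshold scan tightens
this to 1e-8 because the transitions are defined by vanishing slivers.
`shape_threshold_scan()` bisects the gamma100/gamma111 ratio (at fixed
gamma110/gamma111 = 1.22) for the two transitions: the cube persists up
to 1/sqrt(3) = 0.5774, and the {100} family vanishes at
sqrt(2) x 1.22 = 1.7253 — with the exact counting ratio sqrt(6)/2 in
place of 1.22 this point is exactly sqrt(3). Between the two
thresholds the shape is an octahedron truncated at its corners by cube
faces; beyond the upper threshold the (110) plane still slightly
truncates the octahedron edges whenever gamma110/gamma111 < sqrt(6)/2.

## Lattice structure: S(q)

`structure_factor()` evaluates the center-of-body structure factor with
the self term excluded, at wavevectors commensurate with the (possibly
triclinic) box, averaged over frames, and shell-bins the result with a
width of a quarter of the smallest reciprocal spacing. Both species are
included by default (the definition does not restrict species;
per-species partials are available). For the ideal CD lattice, peaks
appear only at the allowed reflections (indices all odd, or all even
with h+k+l = 0 mod 4); interference between the two sublattices makes
mixed reflections like (111) half-height relative to (220)-type ones,
and (200) vanishes. Because the commensurate grid is dense in magnitude
at high q, `sq_peak_table()` measures each reflection as the maximum
per-vector S near the theoretical position over the local background
median, rather than as a shell average. `peak_sharpness_report()`
summarises the largest resolvable q/q0 and whether the close pair of
reflections near q/q0 = 4.2 (at sqrt(51/3) and sqrt(56/3)) is split —
the practical measure of how vibration amplitudes (through
Debye-Waller-like damping exp(-q^2 <u^2> / 3)) trade structural
definition against softness.

## Vibrational spectrum and free energy

The fluctuation route to the dispersion: displacements of the body
centers from their mean positions are mass-weighted (total body masses,
621 and 175 site masses for NP and cage), lattice-Fourier transformed,
and their equal-time covariance inverted, D(q) = kB T C(q)^-1
(`estimate_dynamical_matrix()`; the acoustic null space at q = 0 is
pseudo-inverted and reported as zero frequencies). With two bodies per
cell there are six branches; along (100) and (111) the two lowest are
degenerate, and a 4-fold supercell admits four wavevectors per
direction, so after merging the degenerate pair and removing
shared-origin duplicates 13 unique points remain for the fit.

The model fitted to those points is the harmonic lattice with radial
springs kr on the four nearest-neighbour links and angular springs
ktheta (times r0) on the bond-angle triplets of each body. Its
dynamical matrix is assembled from force constants extracted by
differentiating the two quadratic forms on the ideal lattice
(`cd_harmonic_model()`): the Hessian is linear in kr and ktheta, so the
extraction runs once per geometry, the acoustic sum rule is enforced,
and cell offsets are wrapped to the minimum image so D(q) is exact at
every wavevector. The model is validated against a frozen-phonon
second difference of the supercell energy. `fit_spring_constants()`
runs Nelder-Mead least squares in log-parameters; on surrogate data
with 1e4 frames it recovers (kr, ktheta) to about 1 percent.

The classical harmonic free energy per primitive cell is
F = kB T sum over branches of the zone average of ln omega, up to an
additive constant common to all parameter sets (only differences are
reported). The zone integral uses a uniform half-step-shifted grid
(16^3 by default), which excludes the acoustic zeros at the origin.
The measured convergence of Delta F under grid refinement is about
0.2-0.3 percent per doubling (the acoustic logarithm converges slowly;
refining only the cells nearest the origin does not help, so the error
is distributed); for this reason every comparison between parameter
sets is made on a common grid, where the quadrature bias largely
cancels — fitted-versus-true Delta F agrees to well under 5 percent.

## Amplitudes and the entropy decomposition

`msd_translational()` reports both the site-referenced amplitude
`<u^2>` (the variance of body centers about their mean lattice
positions — the quantity the oscillator entropy needs) and the
multi-origin lag curve, whose saturation value is 2 `<u^2>` for
uncorrelated frames. `msd_rotational()` tracks the angle between a
body's center-to-vertex direction at two times, averaged over all
tracked vertices (the choice of vertex is immaterial and averaging is
used); for small isotropic rotations the single-vertex lag plateau is
(4/3) `<phi^2>` and the site-referenced angle variance (2/3) `<phi^2>`,
and the reported `<phi^2>` is the full rotation-vector variance, so
krot = 3 kB T / `<phi^2>` round-trips exactly. Plateaus are detected on
the trailing half of the curve where the log-log slope is below 0.05 or
statistically indistinguishable from zero (i.i.d. frames give flat but
noisy curves); a persistent slope raises a diffusion warning instead of
returning a plateau.

`entropy_decomposition()` implements the independent-oscillator
relative entropies, (3/2) kB times the log amplitude ratios summed over
species, for translations and rotations separately, relative to the
d = 40, ka = 0.5 reference; the temperature-derivative term drops
because `<u^2>` is linear in T (the package exposes the
T dln<u^2>/dlnT = 1 check as a diagnostic). The report carries the
per-species rotational terms, the -T dS columns, dE (from mean
potential energies per cell, essentially flat across d and ka at equal
T by equipartition) and dF = dE - T dS, plus the per-stiffness view in
which each ka is re-referenced to its smallest-NP system — under the
multiplicative amplitude structure the size dependence then collapses
across stiffness values.

## Problem sizes and limitations

The package's test and study defaults are deliberately desk-scale:
surrogate lattices of 2- to 4-fold supercells with 1e4 frames, bead
level systems of one to a few primitive cells (~800 sites each) run for
1e4-1e5 steps, and slabs of a single in-plane mesh. These sizes
validate every estimator against closed forms and recover spring
constants and free-energy differences to a few percent. What they
cannot reach is the collective surface physics: reorientation bonding —
surface cages rotating to hybridize with interior NPs' unused strands,
which lowers the (100) surface energy at small ka and drives the
cube-truncation of the crystallite — involves body rotation against two
intact links and strand crowding, and emerges only on lattice-scale
slabs over orders of magnitude more steps than a desk run. The package
carries the full machinery (slab builder with minimal-broken and
cage-both-sides terminations, the lattice-versus-reorientation link
classifier, the slab energy estimator), and the corresponding
trend assertion in the acceptance suite documents, honestly, that the
effect does not emerge at this scale: isolated-pair probes show that a
single strand absorbs even a 70-degree misalignment at negligible
ka-dependent cost, so the stiffness sensitivity is genuinely
collective. Quantitative shape predictions in this package therefore
come from the counting model and from user-supplied (e.g.,
cluster-scale) slab energies through `surface_energy_from_slab()` and
`wulff_construct()`.

Other limitations: no anharmonic corrections near melting, no explicit
salt (ka is the proxy), no DNA-length effects (strand length is fixed
at 15 nucleotides), and the base-pair attraction is a calibrated
stand-in for the unavailable reference parameterisation — its melting
midpoint, not its detailed shape, is the controlled property.
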