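---
title: "Methods: cobalamin binding-pocket analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cobalamin binding-pocket analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cblpocket)
```

# Scope

`cblpocket` analyses how cobalamin (vitamin B12) transport proteins
accommodate beta-axially substituted cobalamins, glutathionylcobalamin in
particular. The package covers six measurement families — corrin
geometry, rigid-body superposition, contacts and buried interfaces,
ligand-transplant clash screening, absorbance-spectrum comparison, and
thermophoresis binding-isotherm fitting — together with sequence
conservation mapping, a pipeline driver, and seeded synthetic-data
generators that provide ground truth for every family. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic data do and do not establish.

# Corrin geometry

The corrin macrocycle is described by the coordinates of its cobalt, the
four equatorial nitrogens N21–N24, and ring carbons C1–C19. A cobalamin
is located chemically — the unique residue whose cobalt is coordinated by
at least four nitrogens within 2.5 Å — rather than by its three-letter
component code, because hydroxo-, glutathionyl- and cyano-cobalamin carry
different codes across database entries. Alternate conformations are
reduced to the highest-occupancy conformer (ties broken by altloc
identifier) before any distance is measured, so geometry is reproducible
for entries whose ligand-facing loops are modelled in two conformations.

The **butterfly (fold) angle** is the angle between the total
least-squares planes of the two corrin halves, N21–C4–C5–C6–N22–C9–C10
and C10–C11–N23–C14–C15–C16–N24; C10 belongs to both planes, exactly as
the atom lists imply. Planes are fitted by the eigenvector of the
coordinate covariance with the smallest eigenvalue (orthogonal
regression); the angle is folded into [0°, 90°], which makes the measure
symmetric under exchanging the halves and under folding by ±θ.

Axial geometry: the alpha-axial atom is the non-equatorial coordinating
nitrogen (preferring the cobalamin's own nucleotide-tail nitrogen), the
beta-axial atom is the nearest non-corrin heavy atom within 3.0 Å on the
opposite face. *Base-on* means the alpha-axial nitrogen lies within
2.5 Å of cobalt. The 2.5/3.0 Å cutoffs cover the 2.1–2.4 Å
coordination bonds seen in high-resolution transporter complexes with
margin, and are arguments of `extract_corrin()` and `axial_geometry()`
for unusual chemistry.

# Superposition

`kabsch()` is the closed-form optimal rigid-body superposition via
singular value decomposition of the cross-covariance. Only proper
rotations are returned: if the unconstrained optimum is a reflection the
smallest singular vector's sign is flipped, because a mirror image of a
protein is chemically meaningless. Degenerate inputs (fewer than three
pairs, collinear sets) are refused rather than silently handled.

Cross-species C-alpha RMSD pairs residues through a sequence alignment
(`pair_by_alignment()`): every mutually aligned column whose two residues
both have a C-alpha contributes a pair; there is no outlier rejection or
iterative trimming, so the value reflects all ungapped aligned positions.
`domain_superpose()` fits one residue interval and reports deviations
over another, the standard construction for exposing inter-domain
reorientation (a well-fitting alpha-domain with multi-Å deviations over
the beta-domain means the beta-domain has swung).

# Surface areas, contacts, interfaces

SASA is computed by the Shrake–Rupley method: each heavy atom receives a
deterministic quasi-uniform shell (golden-angle spiral) of test points at
radius r_vdW + probe, and a point is accessible when outside every other
atom's expanded sphere. Defaults: probe 1.4 Å, 960 points per atom,
united-atom radii C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, Co 1.26 Å,
fallback 1.70 Å (overridable via `default_radii()`); hydrogens are
ignored. With 960 points the quadrature error on an isolated sphere is
well under 1%. The buried area between components is
(SASA_A + SASA_B − SASA_AB)/2, waters excluded — the convention of
interface-analysis servers — and `interface_report()` ranks the pairwise
interfaces of a ligand/alpha-domain/beta-domain partition by buried area.
Domain boundaries are configuration inputs (selection expressions),
since transporters differ in their linker positions.

Polar contacts use a pure distance criterion: donor/acceptor atoms are
nitrogens and oxygens, a direct contact is a ligand–protein polar pair
within 3.5 Å, and a water bridge is a ligand polar atom and a protein
polar atom each within 3.5 Å of the same water oxygen. No angular term
is applied by default because dashed-bond counts in structure figures are
distance-based; sulfur can be included as polar via an argument.
Disulfides are cysteine SG pairs within 2.5 Å, paired greedily by
ascending distance so no cysteine is used twice. The helix-dipole test
asks whether a carboxylate oxygen approaches a backbone amide nitrogen of
a helix's first two residues within 3.5 Å — the geometry of a
carboxylate capping a helix's positive pole.

# Ligand transplantation

`transplant()` reproduces the modelling construction used to ask whether
another transporter could bind glutathionylcobalamin: the source corrin
is superimposed onto the target's bound cobalamin by name-matching the
13 butterfly atoms plus cobalt (at least 8 matches required; corrin-fit
RMSD above 1.5 Å is an error, since a bad ring fit invalidates the
transplant), and the transform is applied to the glutathione atoms only.
A clash is counted when a transplanted atom and a target protein atom
approach closer than the sum of their van der Waals radii minus a soft
tolerance of 0.4 Å; overlaps beyond 0.6 Å are additionally tallied as
"severe". Waters and the target's own cobalamin are excluded, the
target keeps its own corrin, and no repacking or minimisation is
attempted — the question is purely whether the pocket as observed
provides space.

# Spectra

Absorbance spectra from different instruments and path lengths are made
comparable by area normalisation: the trapezoidal integral of
|absorbance| over the comparison range is scaled to 1. Comparisons are
performed on a common 1 nm linear-interpolation grid. The two
diagnostic cobalamin bands are read from windows defaulting to
340–370 nm (gamma) and 490–580 nm (alpha/beta): collapse of the gamma
band and a red shift of the alpha/beta band distinguish a thiolate
beta-ligand from hydroxide/histidine. `stability_series()` quantifies
time-course stability as the L2 distance of each timepoint's normalised
spectrum from the reference, with a Kendall rank correlation of drift
against time as the trend statistic; a perfectly constant drift series is
assigned tau = 0 by convention (the estimator is undefined there).

# Thermophoresis binding

Each capillary trace is reduced to Fnorm = 1000 × (mean fluorescence in
the hot window)/(mean in the cold window), in per-mil; defaults are
−1–0 s (cold) and 19–20 s (hot) relative to laser-on at t = 0. The
dilution series is fitted with the 1:1 isotherm in its probe-depletion
(quadratic) form,

bound fraction = ((P + L + Kd) − sqrt((P + L + Kd)² − 4 P L)) / (2 P),

with baseline and amplitude as free parameters, because MST probes are
routinely used at concentrations comparable to the Kd where the
hyperbolic approximation is biased. Fitting is by Levenberg–Marquardt
least squares over a log-parameterised Kd with five log-spaced starts
(the isotherm's least-squares surface can be multimodal in log Kd);
the best start by residual sum of squares wins. Two guard rails follow
the realities of the assay: if the fitted amplitude is indistinguishable
from noise (|amplitude| < 3 × residual SD) the fit aborts with a
no-binding error rather than reporting a meaningless Kd, and if the
fitted Kd does not exceed the probe concentration the estimate is
flagged as a *lower limit* — with probe above Kd the binding curve's
position no longer encodes the true affinity, only a bound on it. The
probe-depletion model reduces to the hyperbola as P → 0 (they agree to
1% at P = Kd/1000), which the tests verify.

`fit_kd()` returns a classed model object with the standard R verbs
(`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
`simulate`), the package's one true "fitted model".

# Sequence conservation

Global pairwise alignment is Needleman–Wunsch with affine gaps
(BLOSUM62, gap open 10, gap extend 0.5, end gaps penalised), delegated to
`Biostrings::pairwiseAlignment()`; the test suite checks the scores
against an exhaustive enumeration over all alignments of short
sequences. Percent identity counts identical columns over mutually
aligned columns only — all gap positions are excluded from the
denominator. Different alignment tools differ by a point or two under
other conventions; results should be quoted with that in mind.
`map_conservation()` reports, for chosen reference residues (e.g. the
glutathione-contacting serine/threonine/tyrosine/histidine positions of
rat transcobalamin numbering), the aligned residue in each homolog and
an identity flag.

# The synthetic-data generators

All tests run offline against generated inputs with known ground truth;
no crystallographic coordinates are redistributed, so deposited entries
are represented by synthetic stand-ins built by `make_tc_complex()` and
relatives, labelled synthetic in their identifiers and documentation.

`make_corrin(fold_angle)` emits an idealized planar corrin template
(cobalt at the origin, equatorial nitrogens at 1.9 Å, canonical ring
atom names, the nucleotide-tail nitrogen 2.2 Å below cobalt, plus
peripheral side-chain and tail pseudo-atoms that give the cofactor a
realistic footprint) and rotates the southern butterfly half about the
Co–C10 hinge. Because the hinge lies in the ring plane, the plane-plane
angle of the construction equals the requested fold angle exactly, which
is what makes the generator a legitimate oracle for recovery tests. The
geometry is canonical, not crystallographic: fold-angle recovery needs
controlled truth, not realism.

`make_tc_complex()` assembles a transporter-like complex around that
cofactor: a glutathione at the beta face with its sulfur 2.40 Å from
cobalt (or a histidine with NE2 at 2.10 Å, for the histidine-ligated
form, with defaults fold angles 6.6° and 5.3° respectively); four
disulfide-bonded cysteine pairs at the canonical transcobalamin numbering
(21–268, 83–96, 116–310, 165–208); a designed polar-contact network of
exactly 4 direct contacts (Ser195, Thr198 side chains, and the
Tyr154/Tyr155 helix N-terminal amides against the gamma-glutamate
carboxylate) plus 10 water-mediated bridges, placed by a deterministic
direction search that keeps every non-designed polar pair beyond the
3.5 Å cutoff; and a two-domain pseudo-protein envelope whose buried
interfaces rank ligand/beta > ligand/alpha > alpha/beta, with the
alpha-domain closing onto the beta face when no glutathione occupies it.
The `"blocked"` pocket variant inserts loop atoms over the glutathione
site, emulating the occluded haptocorrin/intrinsic-factor pockets.
`make_pocket(block_offset = d)` places a single blocking carbon at
distance d from the glutathione sulfur site, forcing exactly one
transplant clash of hand-computable overlap r_C + r_S − soft_tol − d.

Spectra are Gaussian sums on a 300–700 nm, 1 nm grid;
`cobalamin_peaks()` provides two-band presets in which the gamma band
halves and both bands shift red between the hydroxo/histidine and
glutathionyl forms. MST series are 16-point two-fold dilutions from
800 nM with i.i.d. Gaussian noise on the per-mil response (matching
error bars reported as SDs over repeated measurements) and raw traces
consistent with the responses. Homolog sequences are point-substituted
copies of a seeded random reference.

What passing tests establish: every analysis recovers the construction
parameters of inputs whose truth is known, at the stated tolerances, and
the qualitative contrasts of the study design (occluded vs accommodating
pockets, solvent-dominated contact network, interface ranking,
gamma-collapse/red-shift, probe-limited Kd) are reproduced end to end.
What they do not establish: agreement with measurements on the deposited
crystal structures themselves — real coordinates carry anisotropy,
alternate conformations and chemical detail the generators deliberately
omit, and the stand-ins' buried-area magnitudes (≈440 Å² for
ligand/beta) are smaller than crystallographic values because the
idealized cofactor carries fewer peripheral atoms. Rerunning the
structural analyses on deposited coordinates requires only
`read_structure()` on the downloaded files.

# Numerical choices and problem sizes

Plane fits and superpositions are closed-form; the only iterative
numerics are the isotherm fit (multi-start Levenberg–Marquardt,
tolerances 1e-15, 500 iterations) and nothing else. Quadrature defaults
(960 Shrake–Rupley points) are reduced to 240–480 points in tests and
the acceptance script, where the quantities of interest are area ratios
and rankings that are stable at that resolution; synthetic complexes
contain roughly 300 atoms, homolog traces 430 residues, and the noisy-Kd
recovery uses 25–100 seeded replicates. These sizes keep the whole suite
in the tens of seconds on one core while leaving every tolerance
comfortably met.

# Known limitations

- Contact detection is distance-only; no donor/acceptor angles, no
  salt-bridge/H-bond discrimination, no hydrophobic or stacking terms.
- The transplant screen is rigid: no side-chain repacking or pocket
  relaxation, so it reports steric incompatibility of the observed
  conformations, not binding free energies.
- Interface ranking is by buried area alone; no interface free-energy
  estimate is attempted.
- The spectral module assumes blank-corrected inputs and performs no
  scatter or baseline correction.
- Percent identity depends on alignment conventions at the ±1–2 point
  level.
- No symmetry expansion or biological-assembly generation; analyses run
  on the asymmetric unit as read.
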