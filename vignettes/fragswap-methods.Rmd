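---
title: "Methods: fragment demarcation, hybrid design, and enzyme characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment demarcation, hybrid design, and enzyme characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragswap)
```

This vignette documents the models and procedures behind `fragswap`, the
parameters that matter, the numerical choices, and what the synthetic
fixtures do and do not establish about real data.

## Alignment and secondary structure

Fragment demarcation operates on a pairwise global alignment of the two
parent enzymes, annotated per-residue with 3-state secondary structure
(H/E/C). Alignment is Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment()`; a gap run of length $L$ costs
$\mathrm{open} + \mathrm{ext}\cdot L$. Defaults are BLOSUM62, open 10,
extend 0.5 — standard expert defaults for homologs in the ~50% identity
range. Percent identity is computed over aligned (non-gap) residue pairs
only, which is the convention under which two 53%-identical catalytic
domains are described. The emitted column list is self-consistent: the score
recomputed from the columns equals the aligner's score, and on short
sequences the score equals an exhaustive-enumeration optimum (both are
tested).

Secondary structure can be **supplied** (one H/E/C character per residue —
the preferred route when a curated assignment such as DSSP output is
available) or **computed** from backbone coordinates with a deliberately
simple dihedral proxy: a residue is helical when $\phi \in [-100°, -30°]$
and $\psi \in [-80°, -5°]$, extended when $\phi \in [-180°, -60°]$ and
$\psi \in [60°, 180°] \cup [-180°, -150°]$; runs shorter than 4 (helix) or
3 (strand) fall back to coil. Terminal residues have only one of the two
dihedrals and are classified on the available angle, so an ideal 12-residue
helix is labelled H at all 12 positions. This proxy is testable (it is exact
on ideal-geometry fixtures and invariant under rigid motion) but it is not
DSSP: it ignores hydrogen-bond energetics, and real irregular elements
(3-10 helices, bulged strands) will disagree near element boundaries.
Structure-guided *alignment* (superposition) is intentionally not
implemented; SS-annotated sequence alignment is this package's definition of
the demarcation substrate, a simplification worth remembering when the two
parents have low sequence identity but high structural similarity.

## Demarcation: two hard constraints plus an explicit objective

A cut after alignment column $c$ (the junction between columns $c$ and
$c+1$) is **eligible** iff

1. columns $c - w \ldots c + 1 + w$ all exist and are non-gap in both
   parents ($w$ = `eligibility_window`, default 1 column) — junctions are
   kept away from indels, whose counterpart coordinates are ambiguous;
2. the residues at column $c$ are coil on **both** parents;
3. the cut interrupts no helix/strand run on either parent.

A scheme is a subset of eligible cuts whose fragments tile both parents,
with every fragment at least `min_fragment_len` residues (default 5 — a
shorter "fragment" is effectively a point mutation, configurable down to 1)
and every *internal* fragment at most `max_internal_len` residues on **both**
parents. The default cap of 19 encodes a "shorter than 20 residues" rule
strictly; terminal fragments (the N- and C-terminal pieces) are exempt, as
terminal domains conventionally are. Lengths are enforced on both parents
because gapped alignments can make counterpart fragments differ in length.

Published demarcations of this kind are typically manual: the two rules are
stated, but *which* eligible coil regions become boundaries is not. We make
that choice explicit and reproducible with a dynamic program over the
eligible cuts under one of two objectives:

- `max_internal_count` (default): maximize the number of internal fragments;
- `target_count: k`: return a scheme with exactly *k* fragments, or fail
  with the achievable maximum (this is the route for reproducing a known
  fragment count, e.g. ten).

Ties are broken by most-even internal fragment lengths (minimum sum of
squared lengths over both parents), then by leftmost cuts, so the output is
a deterministic function of the inputs and parameters. On alignments of up
to ~60 columns the DP is verified against exhaustive enumeration of all
feasible cut subsets; `validate_scheme()` re-checks every invariant
(tiling, bounds, SS preservation, terminal flags) independently of the
solver and is applied to every scheme the tests emit.

## Chimera assembly, naming, reverse translation, primers

A hybrid is the recipient sequence with the donor's **alignment-mediated
counterpart interval** substituted for each swapped fragment: the donor
residues aligned to the fragment's columns, extended through interior gaps.
Lengths may therefore change under indel-containing alignments; on gap-free
pairs a full swap reproduces the donor exactly and a zero swap is the
identity (both tested). Names are canonical — recipient id, then swapped
fragment labels ascending (`XylE-M3/M6`, never `M6/M3`) — and parseable, so
the name grammar round-trips. Reverse-direction constructs are first-class:
swapping the same fragments back into the other parent only exchanges the
recipient/donor roles.

Reverse translation gives each residue the codon of the parent CDS it came
from (matching how such constructs are actually assembled from the two
parent genes by overlap PCR); residues without a source CDS take a fixed
preferred codon (most-frequent E. coli codons, bundled). Supplied CDSs must
translate exactly to their parent protein, checked codon-by-codon with the
standard genetic code; internal EcoRI/NotI sites (the cloning sites) are
reported as warnings, and no further restriction screening or codon
optimization is attempted.

Junction primers for overlap-extension PCR span each fragment boundary with
at least `min_flank` nucleotides (default 15 nt) on each side; the forward
primer is the sense-strand window and the reverse primer its reverse
complement. Melting temperature is either the Wallace 2+4 rule or SantaLucia
(1998) unified nearest-neighbor thermodynamics at the 1 M Na⁺ reference with
total strand concentration 0.5 µM (non-self-complementary duplex,
$T_m = \Delta H / (\Delta S + R\ln(C_T/4))$). The window grows symmetrically
until the Tm enters `tm_band` or 40 nt is reached; because Tm only grows
with length, a minimal window already above the band stops immediately, and
out-of-band primers are returned flagged with a warning rather than
suppressed. Note that at the 1 M Na⁺ reference a 30–40 nt junction window
typically melts well above a conventional 55–65 °C band; pass a band
appropriate to your Tm model and salt assumptions.

## Kinetics

`fit_michaelis_menten()` offers the double-reciprocal (Lineweaver–Burk) fit
— ordinary least squares of $1/v$ on $1/[S]$, $K_m = \text{slope}/\text{intercept}$,
$V_{max} = 1/\text{intercept}$ — as the default because that is how
polymeric-substrate xylanase kinetics are conventionally reported, and a
nonlinear Levenberg–Marquardt fit of $v = V_{max}[S]/(K_m+[S])$
(`minpack.lm::nlsLM`, initialized at the LB estimate, parameters bounded
below by 0) as the statistically sound cross-check: the reciprocal transform
up-weights the lowest rates, so under multiplicative noise LB estimates are
fragile. On noise-free data the two agree to machine precision (tested);
under 5% CV multiplicative noise the nonlinear fit's median absolute
relative error for both parameters stays under 10% across 200 simulated
datasets. Levenberg–Marquardt is used instead of `stats::nls` specifically
because zero-residual (noise-free) data is a legal and frequent input here.

Degenerate inputs: fewer than 4 distinct substrate concentrations, any
non-positive rate (no reciprocal), or a non-positive LB intercept are
errors; rates constant across $[S]$ drive $K_m$ to the zero boundary and
carry a saturation warning.

Units: with $V_{max}$ in µmol·min⁻¹·mg⁻¹ and the molecular mass in kDa
(= mg/µmol), $k_{cat} = V_{max}\,M/60$ in s⁻¹, and $k_{cat}/K_m$ is in
mL·s⁻¹·mg⁻¹ because a polymeric substrate is quantified by mass
concentration. The mass is a user input (the mature, deglycosylated chain —
glycosylated apparent masses from SDS-PAGE are the wrong quantity here);
when absent it is computed from the sequence with average residue masses and
the choice is logged via a message. `kinetics_consistency()` audits a
published table's internal arithmetic and *reports* discrepancies — in the
bundled reference table exactly one hybrid row disagrees with its own
printed $k_{cat}/K_m$ (860/0.61 ≈ 1410, printed 1340), and that row is
excluded from arithmetic checks rather than corrected toward either number.

## Thermal stability

T50 — the pre-incubation temperature at which half the maximal activity
survives a fixed heating period — is defined operationally, without a model,
in most enzymology papers. We declare a model: a 2-parameter falling
logistic on the percent scale, $R(T) = 100/(1+\exp((T-T_{50})/s))$, fit by
Levenberg–Marquardt with $T_{50}$ constrained to the assayed range and
$s > 0$, initialized at the interpolated 50% crossing. A model-free
alternative (`method = "interpolation"`: linear interpolation of the 50%
crossing) is provided for data that are not logistic-shaped. Data that never
cross 50% within the assayed range are an extrapolation error, not an
estimate. Half-life assumes first-order decay, fit on the log scale;
non-positive residual activities are a domain error and a non-positive
fitted rate yields `t_half = Inf` with a "no decay" warning. Both fits
recover planted values exactly on noise-free fixtures over a grid of planted
parameters (tested at absolute tolerances of 10⁻⁶ °C and 10⁻⁹ h).

Calorimetric melting temperatures (Tm) are an external DSC measurement:
they are stored in the bundled reference table as data and never computed.
Assay conditions (pH, temperature) are metadata recorded verbatim from
input files, never inferred — source tables in this literature are not
always internally consistent about them.

## Degree of synergy

$DS(t) = Y_{1+2}(t)\,/\,(Y_1(t) + Y_2(t))$, the reducing sugar released by
the simultaneous xylanase + cellulase treatment over the sum of the
single-enzyme yields; $DS > 1$ indicates synergy. The formula as published
has no control term, so no control subtraction is applied by default; a
`subtract_control` flag uses the no-enzyme arm when present. Time points
with a non-positive denominator are skipped with a warning. DS is invariant
to rescaling all arms by a common factor (tested). At the published 15-hour
yields of the best hybrid (3.9 vs 3.2 + 0.45 µmol/mL) the package computes
$DS = 1.068$; the higher curve maximum of ~1.3 reported graphically occurs
at time points whose arm values are not printed and is therefore not
desk-reproducible — the package makes no attempt to match it.

## Hydrogen-bond occupancy

A donor–hydrogen–acceptor triple is a bond iff the donor–acceptor heavy-atom
distance is ≤ 3.5 Å and the D–H–A angle is ≥ 120° (both parameters; these
defaults are the common geometric convention — the source analyses in this
literature rarely publish their criteria). Donors and acceptors come from a
per-residue catalogue (backbone N except proline / backbone O, plus polar
side chains); hydrogens attach to their donor geometrically (≤ 1.25 Å).
Frames without hydrogens — typical crystallographic input — fall back to the
distance criterion alone and the output is flagged. Occupancy of a pair is
the percentage of window frames in which it is bonded via any hydrogen;
windows can be index vectors or `"last:25%"`-style strings, matching the
common practice of analyzing the equilibrated tail of a trajectory.
Detection matches a brute-force all-pairs oracle on every fixture frame and
is rigid-motion invariant; occupancy over a union of disjoint windows equals
the frame-weighted mean of the per-window occupancies (all tested). Running
dynamics, energy-based bond definitions, and binding-energy decompositions
are out of scope.

## Synthetic fixtures: what they establish and what they cannot

Every generator is deterministic under its seed (Mersenne-Twister, locally
scoped so callers' RNG state is untouched), returns its planted truth, and
`write_fixture()` emits the data in standard formats plus a `truth.json`.

- `make_parent_pair()` draws parent A uniformly over the 20 amino acids and
  derives parent B by substituting a fixed fraction of positions and placing
  single-residue indels only in interior coil runs. With 47% divergence it
  reproduces the ~53%-identity regime of a real mesophile/thermophile pair.
  It does **not** emulate real substitution processes (no BLOSUM-like
  exchange preferences, no rate variation), so passing demarcation tests
  show algorithmic correctness, not robustness to biological alignment
  ambiguity.
- `make_kinetics()` uses multiplicative Gaussian noise (CV-parameterized),
  matching how assay replicate scatter scales with signal;
  `make_t50()`/`make_decay()` use additive noise on the percent scale
  truncated to [0, 110]%. Real assays add systematic errors (pipetting
  bias, substrate batch effects) that no noise model here represents.
- `make_synergy()` is parameterized directly by a target DS(t) profile plus
  arm trajectories, so `degree_of_synergy()` has a closed-form oracle; noise
  is a shared per-timepoint factor, which preserves DS exactly.
- `make_trajectory()` plants bonds with ideal linear geometry (2.9 Å,
  180°) on scheduled frames and displaces the acceptor to 6 Å otherwise,
  with decoys ≥ 8 Å from everything. Occupancy recovery on it is exact by
  construction; it says nothing about borderline geometries near the
  criteria thresholds, which is where criterion choice matters on real
  trajectories.

Problem sizes used by the test suite and the acceptance script — 123-residue
parent pairs, alignments ≤ 60 columns for the exhaustive demarcation
cross-checks, 200 noisy kinetics datasets, 20-frame trajectories — were
chosen as the smallest sizes at which every contract is exercised
non-trivially; all scale linearly or quadratically if increased.

## Known limitations

- Sequence-only alignment with SS annotation approximates a
  structure-guided alignment; for remote homologs supply a curated alignment
  -equivalent SS annotation or expect boundary shifts.
- The dihedral SS proxy disagrees with DSSP near element termini.
- The mature-protein numbering offset between author numbering and internal
  1-based numbering is a user responsibility (`res_seq` in structures is
  taken at face value); no renumbering heuristics are applied.
- LB standard errors are delta-method approximations; for inference use the
  nonlinear fit.
- Primer design checks uniqueness and Tm only; no secondary-structure,
  dimer, or mispriming screens.
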