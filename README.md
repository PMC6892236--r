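# fragswap

Fragment-replacement design and quantitative characterization of hybrid
enzymes.

## The problem

A recurring trade-off in enzyme engineering is that mutations which raise
catalytic activity often cost thermostability, and vice versa. One strategy
that can improve both at once is **fragment replacement**: align two
homologous enzymes — a mesophilic workhorse and a thermostable homolog —
partition them into short, structurally equivalent peptide fragments, and
swap selected fragments of the stable parent into the active one (or the
reverse). The canonical application is a pair of GH10 endo-xylanases (XylE
and its thermophilic homolog XYL10C, ~53% identical), where swapping three
internal fragments, alone and in combination, produced hybrids with several-fold
higher catalytic efficiency and a higher inactivation midpoint.

`fragswap` implements the design side of that strategy and the full
measurement toolkit used to judge the resulting hybrids:

- **Demarcation.** Fragment boundaries are chosen on a pairwise global
  alignment (Needleman–Wunsch, affine gaps, BLOSUM62) annotated with 3-state
  secondary structure, under two hard constraints: a boundary may only fall
  where *both* parents are coil (so no helix or strand is interrupted), and
  every internal fragment is at most `max_internal_len` residues (default 19,
  i.e. "shorter than 20") on *both* parents. Which eligible coil columns
  become boundaries is decided by a small dynamic program — either maximizing
  the number of internal fragments or hitting an exact target count
  (ties: most-even internal lengths, then leftmost cuts).
- **Chimera generation.** Single, set, and combinatorial
  (all non-empty subsets) fragment swaps in either direction, with
  per-residue provenance and canonical names (`XylE-M3/M6`, donor fragments
  in ascending order). Reverse translation inherits codons from the parent
  CDSs, and overlap-extension PCR junction primers are designed with
  Wallace or SantaLucia nearest-neighbor melting temperatures.
- **Kinetics.** Michaelis–Menten fits by Lineweaver–Burk (the conventional
  reporting route for polymeric substrates) and by nonlinear least squares;
  `kcat = Vmax × MW(kDa) / 60`, catalytic efficiency `kcat/Km` in mL/s/mg,
  fold-change summaries, and an arithmetic-consistency audit for published
  kinetics tables.
- **Thermal stability.** T50 (logistic midpoint of residual activity vs
  pre-incubation temperature, `R(T) = 100/(1+exp((T−T50)/s))`) and
  first-order half-life (`ln R = ln R0 − kt`, `t½ = ln2/k`).
- **Synergy.** Degree of synergy for mixed xylanase + cellulase hydrolysis,
  `DS(t) = Y_both / (Y_cellulase + Y_xylanase)`.
- **Structure post-processing.** Geometric hydrogen-bond detection
  (donor–acceptor ≤ 3.5 Å, D–H–A ≥ 120° by default) and frame-fraction
  occupancy over multi-model PDB trajectories.
- **Synthetic fixtures.** Deterministic generators for parent pairs with
  designed secondary structure, ideal-geometry backbones, kinetics / thermal
  / synergy datasets with planted parameters, and trajectories with planted
  hydrogen-bond schedules — every estimator can be validated offline against
  known truth.

## Worked example

```r
library(fragswap)

# a synthetic parent pair in the 53%-identity regime, with a secondary-
# structure layout that admits a ten-fragment scheme
lay <- ss_layout_for_fragments(10)
pp  <- make_parent_pair(seed = 42, length = nchar(lay), ss_layout = lay,
                        divergence_pct = 47)
ap  <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
ap
#> <aligned_parents> parentA (123 aa) vs parentB (123 aa)
#>   123 columns, identity 52.8%, score 295.0 (BLOSUM62, open 10, extend 0.5)

scheme <- partition_fragments(ap, demarcation_params(objective = "target_count",
                                                     target_count = 10))
scheme
#> <fragment_scheme> 10 fragments of parentA / parentB (max internal len 19)
#>  name a_start a_end b_start b_end terminal
#>    M1       1     5       1     5     TRUE
#>    M2       6    17       6    17    FALSE
#>    ...
#>   M10     107   123     107   123     TRUE

# all seven combinations of three key fragments
cc <- generate_chimeras(scheme, ap, "parentA", c("M3", "M6", "M9"),
                        mode = "combinations")
cc[[7]]
#> <chimera_construct> parentA-M3/M6/M9: 123 aa, 38 donor residues (M3/M6/M9 from parentB)

# kinetics: fit, then derive the full characterization row
fit <- fit_michaelis_menten(make_kinetics(1, km = 0.75, vmax = 680)$table)
fit
#> <mm_fit> lineweaver_burk: Km = 0.75 mg/mL, Vmax = 680 umol/min/mg (R^2 = 1.0000)
kinetics_summary(fit, mw_kda = 37.9, specific_activity = 610)[c("kcat", "kcat_over_Km")]
#> $kcat        429.5333   # /s
#> $kcat_over_Km 572.7111  # mL/s/mg

# thermal stability
fit_t50(make_t50(1, t50 = 66.5, s = 2)$table)
#> <t50_fit> logistic: T50 = 66.5 C, slope = 2 C
fit_half_life(make_decay(1, t_half = 1.2)$table)
#> <decay_fit> k = 0.5776 /h, t1/2 = 1.2 h (R^2 = 1.0000)

# degree of synergy at the published 15-h yields of the best hybrid
degree_of_synergy(data.frame(time_h = 15, both = 3.9,
                             cellulase_only = 3.2, xylanase_only = 0.45))
#> <synergy_ds> 1 time points; max DS = 1.068 at 15 h; first DS > 1 at 15 h
```

The planted values above (Km 0.75 mg/mL, Vmax 680 µmol/min/mg, T50 66.5 °C,
t½ 1.2 h) are the wild-type XylE characterization values; the fits recover
them exactly from noise-free synthetic data, and the derived kcat (429.5 /s)
and kcat/Km (572.7 mL/s/mg) agree with the published 430 and 570 within
printed rounding. A DS of 1.068 (> 1) at 15 h quantifies xylanase–cellulase
synergy on lignocellulose.

A bundled reference table of the published characterization of the
XylE/XYL10C hybrid family is available via `xyle_reference_tables()`.

## Command line

A thin CLI over the same functions is installed at
`system.file("cli", "fragswap.R", package = "fragswap")`:

```sh
Rscript fragswap.R demarcate --parents a.fasta,b.fasta --ss parents.ss -o scheme.tsv
Rscript fragswap.R chimera --parents a.fasta,b.fasta --scheme scheme.tsv \
    --recipient parentA --combinations M3,M6,M9 -o hybrids.fasta
Rscript fragswap.R kinetics --in rates.csv --mw-kda 37.9 -o row.tsv
Rscript fragswap.R hbond --frames traj.pdb --window last:25% -o occupancy.tsv
Rscript fragswap.R simulate --kind kinetics --seed 7 --km 0.75 --vmax 680 -o sim/
```

## Scope notes

Wet-lab quantities are inputs here, never outputs: measured specific
activities, DSC melting temperatures (Tm), HPLC product profiles, and
MM/PBSA binding energies are stored as data where useful. Structure-based
alignment, full DSSP, codon optimization, and running molecular dynamics are
out of scope; see the methods vignette (`vignettes/fragswap-methods.Rmd`)
for the modeling choices and their limitations.
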