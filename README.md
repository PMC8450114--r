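# holocsim

Loop-extrusion and polymer simulation of holocentric chromosome condensation.

## The problem

Most chromosomes carry one centromere, visible at metaphase as a primary
constriction. In many independent lineages (nematodes such as *C. elegans*,
plants such as *Luzula* and *Rhynchospora*) chromosomes are *holocentric*:
centromeric (CENH3-containing) nucleosomes are dispersed chromosome-wide
during interphase, yet at metaphase they assemble into a continuous
line-like centromere along each chromatid, in some species at the bottom of
a longitudinal groove. `holocsim` implements a minimal mechanistic model of
that assembly for people studying chromosome organization by simulation:
the only actors are loop extruders (LEs; SMC complexes such as condensin),
centromeric nucleosomes that modulate LE motion, and optionally a rigid
kinetochore plate.

## The model

A chromosome is a chain of `N` nucleosomes (~200 bp each; full scale
`N = 100000`, ~20 Mb). The 1D stage simulates two-sided loop extrusion on
the lattice: each LE binds an adjacent pair and moves its legs outward one
site per step; legs block on other LEs, on chromosome ends and — in the
`blocking` and `anchoring` modes — on centromeric nucleosomes. An LE
unbinds with per-step probability `1/lifetime` and rebinds at a random free
adjacent pair; in `anchoring` mode an LE arrested at a centromeric
nucleosome is never released. Condensation is quantified by the *axial
nucleosomes* (LE-bound sites outside all other loops; their count is the
chromosome length), the *average loop length* `sum(right - left - 1) /
n_les`, and the fraction of nucleosomes outside loops.

The 3D stage replays the 1D bond list (one 1D step per block of 100 3D
steps) on a bead-spring fibre with harmonic bonds (10 nm mean, 1 nm
wiggle), angular stiffness `1 kBT (1 - cos theta)`, and a soft-core
repulsion of 5 kBT up to 10.5 nm that lets strands cross (topoisomerase
II-like); LE bonds are harmonic (5 nm, 0.5 kBT/nm^2). Integration is
fixed-step BAOAB Langevin in reduced units. The kinetochore stage tethers
centromeric nucleosomes and an impassable plate of beads (10000 kBT
barrier) and verifies that chromatin never crosses it.

With anchoring centromeres the model condenses a holocentric chromosome to
a plateau length set by the centromere count (one or two loops between
adjacent centromeric nucleosomes), aligns the centromeres into a genomic-
order line, and — with the plate — leaves a chromatin-free groove behind
the kinetochore. Clustered (monocentric) centromeres instead give a longer
chromosome with small loops confined to the centromeric region.

## Worked example

A one-tenth-scale holocentric chromosome (10000 nucleosomes, 10 anchoring
centromeres, 100 LEs, lifetime 1000, 60000 steps):

```r
library(holocsim)
spec   <- holocentric_spec(10000, 10, seed = 1)
params <- extrusion_params(100, lifetime = 1000, mode = "anchoring",
                           n_steps = 60000, seed = 1)
trace  <- run_extrusion(spec, params)
round(equilibrium_summary(trace), 2)
#>   chromosome_length avg_loop_length frac_outside n_side_by_side
#> 1              43.6          306.51            0           21.8
#>   chromosome_length_final avg_loop_length_final frac_outside_final
#> 1                      38                309.84                  0
#>   n_side_by_side_final
#> 1                   19
loops_per_interval(final_state(trace), spec)
#> [1] 2 2 2 2 2 2 1 2 2
```

The chromosome settles at ~40 axial nucleosomes — the anchoring plateau,
here 2 legs x ~2 loops per inter-centromere interval — with one or two
side-by-side loops between every pair of adjacent centromeres and ~0.1% of
nucleosomes (essentially the centromeric ones) outside loops. The average
loop is ~300 nucleosomes (~60 kb). `run_dynamics()` /
`run_kinetochore_dynamics()` turn such traces into 3D conformations, and
`contact_map()`, `contact_probability()`, `axial_spacing()`,
`centromere_spacing_histogram()` and `groove_profile()` analyse them.
`preset()` + `run_experiment()` bundle the shipped experiment recipes
(`le_sweep`, `holo_line`, `holo_vs_mono`, `groove`).

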