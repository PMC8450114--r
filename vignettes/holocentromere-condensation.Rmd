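---
title: "Modelling holocentric chromosome condensation with loop extruders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling holocentric chromosome condensation with loop extruders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`holocsim` studies how a chromosome that carries many dispersed centromeric
nucleosomes (a holocentric chromosome, as in *C. elegans*, *Luzula* or
*Rhynchospora*) can condense into a chromatid with a continuous, line-like
centromere, while a chromosome with a single clustered centromere region (a
monocentric chromosome) condenses into a longer body with a constriction. The
only ingredients are:

* a chromatin fibre of `N` nucleosomes (one bead per nucleosome, ~200 bp
  each; the default full-scale chromosome has `N = 100000`, about 20 Mb);
* loop extruders (LEs) standing in for SMC complexes such as condensin: an
  LE binds two adjacent nucleosomes and reels chromatin symmetrically,
  extruding a loop, until it unbinds and rebinds elsewhere;
* centromeric nucleosomes that differ from all others *only* in how they
  interact with LEs.

The simulation is two-level. A 1D lattice simulation decides, step by step,
which nucleosome pairs the LEs bind. A 3D Langevin polymer simulation then
replays those bonds on a bead-spring fibre to produce conformations, which
the analysis module turns into spacing histograms, contact maps, contact
probability curves and groove profiles.

## The 1D extrusion rules

Each LE occupies a pair of lattice sites `(left, right)`. Once per 1D step
each leg moves one site outward unless the destination is (a) occupied by
another LE leg, (b) a centromeric site in the blocking/anchoring modes, or
(c) a chromosome end. Both legs of an LE attempt their move in the same
sub-step; LEs are updated in a fresh random permutation each step so no
index order is privileged. LEs cannot traverse each other, and a blocked leg
simply waits.

Unbinding is a per-step Bernoulli event with probability `1/lifetime`
(default lifetime 1000 steps). An unbound LE rebinds immediately at a
uniformly random free adjacent pair, so the number of LEs on the fibre is
constant. Rebinding uses rejection sampling with a bounded number of draws;
in the (never observed at realistic occupancy) case that no free pair is
found, the LE waits one step where it was.

The three centromere modes:

* **none** — centromeric sites are ordinary sites;
* **blocking** — a leg can never step onto a centromeric site, so the
  approaching side of the LE arrests while the other side keeps reeling; the
  LE may still unbind;
* **anchoring** — blocking, plus an LE with at least one leg arrested
  against a centromeric site is never released, no matter its age.

Design points the rules leave open, and the choices made here: an LE whose
leg is blocked by *another LE* (not a centromere) still unbinds normally in
every mode; rebinding may land anywhere on the chromosome, including inside
existing loops; chromosome ends block motion but neither anchor nor release
LEs. The engine draws all randomness from R's RNG in a fixed documented
order, so runs are bit-reproducible under a seed, and the test suite holds
the compiled engine to state-for-state equality with a plain R interpreter
of the same rules.

## Condensation metrics

*Axial nucleosomes* are LE-bound sites that are not strictly inside any
other LE's loop span; their count is the 1D chromosome length. Without
nesting it equals twice the number of LEs. The *average loop length* is the
mean number of nucleosomes strictly between the bound pairs; nucleosomes
inside nested loops count once per enclosing loop, so `loop length x n_les`
can exceed `N` in deeply nested states — the formula is applied literally.
The *fraction outside loops* is the fraction of sites covered by no loop
span. A state is *sparse* when `avg_loop x n_les < N` (ties compacted).
*Side-by-side loops* are the non-nested loops; `loops_per_interval()` counts
them between adjacent centromeric sites.

Equilibrium is declared when the windowed means of chromosome length and
loop length over the last two windows (default window: 10% of the run)
agree within 5% relatively; summaries average the last half of the run and
are reported over 10 replicate seeds, mean and SD.

## Centromere layouts

The holocentric generator draws centromere positions uniformly at random
without replacement, which is the package default; a deterministic
even-spacing option (`even = TRUE`) places them at interval midpoints. The
distinction matters: random layouts contain short inter-centromere gaps that
tend to seal with a *single* anchored loop (a lone LE reaches both flanking
centromeres before a second LE lands in the gap), while even spacing gives
every interval the time to capture two LEs. Counts of side-by-side loops are
therefore somewhat below the idealized two-per-interval picture under the
random default, and condensed chromosome lengths a little below the
even-layout value of twice the LE-pair bound. The monocentric generator
confines its centromeres to a contiguous window (default 400 kb worth of
sites) centred on the chromosome; centring avoids conflating the centromere
constriction with chromosome-end effects.

## The 3D stage

Reduced units: lengths in nm, energies in kBT, bead mass 1. The force field
is (i) harmonic backbone bonds, mean 10 nm, spring constant `1/wiggle^2`
with wiggle 1 nm (so thermal bond fluctuations have ~1 nm SD); (ii) an
angular stiffness `k (1 - cos theta)` with `k = 1` kBT on consecutive bond
vectors; (iii) a soft-core repulsion `E (1 - (r/rc)^2)^2` for `r < rc`,
`rc = 10.5` nm, with `E = 5` kBT between chromatin beads — a finite overlap
barrier that lets strands pass through each other at a finite rate, playing
the role of topoisomerase II. Directly bonded neighbours are excluded from
the repulsion so the backbone minimum is exactly 10 nm. LE bonds are
harmonic with 5 nm mean and 0.5 kBT/nm^2 constant, updated every block of
3D steps (default 100) from the 1D trace, one 1D step per block. A standard
run starts from a random-walk coil, runs 10000 blocks without LE bonds and
then 40000 blocks with them (scaled runs shrink all of these together).

The integrator is fixed-step BAOAB Langevin (default `dt = 0.08`, friction
0.5 in reduced units). A fixed step makes trajectories exactly reproducible
under a seed and, with friction 0, reduces to velocity Verlet, which the
test suite uses to verify energy conservation. The dynamics are only asked
to reach conformational equilibrium; no real-time mapping is claimed.

## The kinetochore stage

The kinetochore is a rigid plate: beads with fixed positions on a
rectangular grid parallel to the centromeric line. Centromeric nucleosomes
are tethered to their initial line positions by 5 kBT/nm^2 harmonic wells.
Repulsion involving a kinetochore bead uses a 10000 kBT barrier, making the
plate impassable to chromatin; a crossing counter verifies that no chromatin
bead ever passes through the plate interior (beads skimming around the plate
edge are not crossings and are not counted). The plate beads are frozen
rather than tethered: a harmonic well soft enough to act as a tether is
overwhelmed by the impassable-barrier contact forces, so a tethered plate
deforms under chromatin pressure and transiently opens holes, which defeats
its purpose as a rigid multiprotein structure. Because the plate barrier is
three orders of magnitude stiffer than the chromatin-chromatin one,
kinetochore runs default to a smaller time step (`dt = 0.02`).

Published descriptions fix the grid length (proportional to the number of
centromeric nucleosomes) but not its width or offset, so those are package
choices, exposed as parameters: bead spacing 10 nm; plate offset 12 nm from
the centromeric line, just outside the repulsion cutoff, so the tethered
centromeres do not start inside the impassable barrier; default width 5
bead rows, and wider plates (9 rows in the shipped groove analyses) when
the plate is meant to span the chromatid face, as a plate-like multiprotein
complex does. The starting conformation aligns the centromeres (and, for a
monocentric chromosome, the axial nucleosomes outside the centromere
region) along the z-axis at 10 nm spacing and folds every loop into a
straight out-and-back excursion along +x; the kinetochore run then replays
the second half of a 100000-step 1D trace, so loop extrusion continues on
an already-equilibrated loop structure.

The *groove statistic* quantifies the chromatin-free furrow: the bead count
in the rectangular shadow box directly behind the plate (beyond the plate
plane, within its footprint, one plate half-width deep) divided by the
count in the mirrored box on the chromatin side. Ratios near 0 mean a
groove. A half-space statistic would be misleading, because loops
legitimately wrap around the plate edges and fill space far behind it; the
furrow of interest is the shadowed region the plate itself protects. In the
monocentric variant the centromeric loops are an order of magnitude too
small to embrace the plate at all, so both boxes stay nearly empty — "no
groove" there means the plate is not embedded in chromatin, which the tests
assert by comparing embracing bead counts against the holocentric run.

## What the generator does and does not emulate

The synthetic chromosome reproduces the study conditions: single chromatin
fibre, uniform nucleosome spacing, centromeres distinguished only through
LE interactions, no volume confinement, no microtubules, no sister
chromatid, no eu/heterochromatin distinction, and LE kinetics reduced to
two parameters (count and lifetime). Passing tests therefore demonstrate
the internal consistency of this mechanism — anchoring suffices to align
centromeres into a line whose length is set by the centromere count, while
clustering them produces a constriction and a longer chromosome — not that
real chromosomes are quantitatively described; real kinetochore geometry,
condensin heterogeneity and nuclear crowding are all outside the model.

## Numerical choices and problem sizes

1D runs at full scale (100000 sites, up to 1000 LEs, 100000 steps) take
seconds via the compiled engine, so the acceptance script recomputes every
headline quantity at full scale with 10 replicate seeds. 3D properties are
verified on reduced systems (5000 beads, 20000-step traces, 1500-3000
blocks of 25-50 steps), sizes chosen so the full pipeline — extrusion,
compaction, line formation, kinetochore groove — runs on a single desktop
core in minutes while keeping the measured properties (monotone centromere
ordering along the chromosome axis, zero plate crossings, shadow-box
depletion) well away from their thresholds. Centromere order is measured
against a locally fitted axis (a window of genomic neighbours), because the
condensed chromosome is a curved cylinder: a single straight principal axis
scores a bent but perfectly ordered line as disordered, and shortened desk-
scale runs can trap long-lived global folds that full-length relaxation
would anneal. Degenerate inputs are rejected
at construction time (empty bond lists, inconsistent traces, regions
outside the chromosome); ties in the sparse/compacted boundary go to
"compacted"; the contact radius applies to bead centres.

## Known limitations

* The blocking/anchoring dichotomy is sharp; real centromere-SMC affinities
  may be partial or transient.
* The soft-core repulsion shape is one smooth polynomial consistent with
  the stated range and barrier; other shapes with the same range/height are
  config-swappable and would change strand-passage rates somewhat.
* Average loop length double-counts nested loops by construction of the
  span-sum formula; interpret it as a per-LE span average, not a partition
  of the chromosome.
* Quantities that depend on the density of short inter-centromere gaps
  (side-by-side loop counts, centromere-region loop sizes) are sensitive to
  the random-versus-even layout choice discussed above.
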