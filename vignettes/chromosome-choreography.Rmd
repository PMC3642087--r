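---
title: "The chromosome-segregation choreography model and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The chromosome-segregation choreography model and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociseg)
```

## The biological picture

`fociseg` models the intracellular choreography of a bacterial chromosome
that is longitudinally organized along the oriC–dif axis, as in
*Pseudomonas aeruginosa*: the origin-proximal ~1.4 Mb (the **Ori region**)
segregates early to fixed positions at 0.2/0.8 of the cell length; the
~800 kb around the dimer-resolution site *dif* (the **Ter region**) stays
near the new pole in newborns, is relocated to mid-cell before replication,
and remains visibly cohesive until around division; arm loci in between
interpolate. Replication takes place in a mostly colocalized replisome
focus near mid-cell, and loci are recruited there shortly before their
replication time. At division, the mid-cell position — where the *dif*
region sits — becomes the new pole of each daughter, which is what makes
orientation by a terminus-proximal marker possible.

The package provides (i) a deterministic core for this choreography, (ii) a
stochastic snapshot simulator with a microscopy observation model, and
(iii) the complete analysis pipeline used on foci tables from snapshot
experiments: focus counting, new-pole orientation, size-binned segregation
curves, median/quartile position summaries, interfocal colocalization,
replisome summaries, and Ori/Arm/Ter region classification.

## The deterministic core

A locus at offset $x$ kb from oriC (on either replichore; the two arms are
treated symmetrically) is replicated at age

$$t_{\mathrm{rep}}(x) = a_{\mathrm{init}} + C \cdot x / x_{\mathrm{half}},$$

with $a_{\mathrm{init}} < 0$ meaning initiation in the mother before
division. Its final new-pole-copy position $p(x)$ is piecewise linear:
$p_{\mathrm{ori}} = 0.2$ for $x \le x_{\mathrm{ori}}$, $0.5$ for
$x \ge x_{\mathrm{ter}}$, interpolated in between; the second copy mirrors
it at $1 - p(x)$. Within one cycle a locus (Ter region excepted) rests at
its inherited position $1 - 2 p(x)$, moves linearly to mid-cell during the
`reloc_lead_min` minutes before $t_{\mathrm{rep}}$, stays one cohesive
focus at mid-cell for `t_coh_min`, then the two copies move linearly to
their final positions over `seg_dur_min`. Ter-region loci instead remain
cohesive at mid-cell and only separate — symmetrically, by a fixed
`ter_sep_offset` — late in the cycle, in the fraction `p_ter_sep` of cells
that carry the per-cell separation flag. Linear-in-time trajectories are an
interpolation choice: only the endpoints are constrained by observation.

Snapshot populations are sampled from the steady-state age density
$f(a) = (2\ln 2/\tau)\, 2^{-a/\tau}$ and grown exponentially,
$L = L_0\, 2^{a/\tau}$, with lognormal newborn-length noise
(CV `len_cv`). Division-septum placement noise is *folded into* this CV:
in a snapshot model without lineage information the two noise sources are
unidentifiable, so a separate septum parameter would be pure redundancy.

## The observation model

Observed foci are produced from true positions by, in order: per-focus
detection (`p_det`), Gaussian axial localization noise (`sigma_pos_um`),
single-linkage merging of foci closer than the optical merge distance
(`d_res_um`, clusters reported at their centroid), whole-cell detection
failure (`p_cellfail`), clipping to the cell, and reporting from a randomly
chosen end so that polarity is hidden. The merge step is what renders
cohesive pairs — and, importantly, the slowly separating copies of
terminus-ward arm loci — as a single focus.

## Parameter defaults and how they were chosen

Units are minutes, micrometers and kb; positions are relative cell lengths
(0 = new pole).

| parameter | citrate | glucose_caa | rationale |
|---|---|---|---|
| `tau_min` | 50 | 45 | doubling times of the two growth conditions |
| `L0_um`, `len_cv` | 2.09, 0.10 | 2.2, 0.10 | mean steady-state size $2\ln 2 \cdot L_0 \approx 2.9\,\mu m$; sizes 2–5 µm |
| `C_min` | 45 | 45 | replication spans most of the cycle |
| `a_init_min` | −5 | −14.8 | initiation slightly before division (citrate); overlapping rounds (rich) |
| `ori_edge_kb` | 900 | 900 | brackets the last Ori-behaving marker (851 kb) and the first arm marker (1509 kb) |
| `ter_edge_kb` | 2600 | 2600 | brackets 2499 kb (arm) and 2672 kb (Ter) |
| `p_ori` | 0.2 | 0.2 | the 0.2/0.8 destination of Ori-region loci |
| `t_coh_min`, `seg_dur_min` | 2, 4 | 2, 4 | see calibration below |
| `p_ter_sep`, `ter_sep_offset`, `ter_late_min` | 0.40, 0.10, 5 | — | keeps Ter two-focus fractions ≤ 50% in every size bin |
| `sigma_pos_um`, `p_det`, `d_res_um`, `p_cellfail` | 0.08, 0.96, 0.30, 0.05 | same | see calibration below |
| `p_fork_split`, split range, `next_round_min` | 0.06, 0.15–0.35, 2 | 0.20 | >90% one-focus replisome cells; occasional 0.2/0.8 pairs pre-division |
| `a2_init_min`, `p_rep2_two`, `p_ter_sep_rich` | — | τ + a_init = 30.2, 0.85, 1/3 | overlapping-round structure; fitted (below) |

**Closed-form calibration.** Several defaults were fixed *a priori* by
quadrature against the steady-state age law rather than by trial
simulation. Three worked examples:

* *Detection ceiling.* Among cells whose locus pair is truly resolved, the
  observed two-focus fraction among focus-positive cells cannot exceed
  $p_{\mathrm{det}}^2 / (1 - (1-p_{\mathrm{det}})^2)$. For the >90%
  two-focus claim of origin-proximal loci to be reproducible with margin,
  this ceiling must clear 0.90 comfortably: $p_{\mathrm{det}} = 0.96$
  gives 0.923 (0.95 gives only 0.905).
* *Cohesion and segregation must complete before birth for Ori loci.* The
  82-kb locus is replicated at $t_{\mathrm{rep}} = -3.83$; for its two
  copies to be separated at birth (the observed situation), cohesion plus
  the time to exceed the merge distance must fit into 3.83 minutes, hence
  `t_coh_min = 2` and `seg_dur_min = 4` (resolution at ≈ −0.9 min).
* *Replisome one-focus fraction.* With the replication window $[0, 40]$,
  a fork-split probability $q$ and a pre-division window $\epsilon$ for
  next-round foci, the two-focus fraction among focus-positive cells is
  approximately $0.85 q + 0.9 \Pr(a > \tau - \epsilon)$; $q = 0.06$,
  $\epsilon = 2$ keeps it below 10%.

Two rich-medium parameters are *fitted, not predicted*: `p_rep2_two = 0.85`
reproduces the ~65% two-focus replisome fraction among cells > 3.5 µm
(the fit must absorb the large cells whose second round has not yet
initiated because of newborn-size spread), and `p_ter_sep_rich = 1/3`
reproduces the observed 2:1 ratio of (4 Ori, 1 Ter) to (4 Ori, 2 Ter)
cells. The `par_null` mode is purely descriptive: a categorical focus-count
distribution with ≥ 50% mass on zero plus uniform positions, reproducing
the disorganization phenotype, not its mechanism.

## Region edges are parameters, not measurements

Twenty markers bracket, but do not measure, the extent of the two
distinctive regions. `ori_edge_kb = 900` sits between the outermost
0.2/0.8-targeting marker (851 kb) and the innermost arm-behaving marker
(1509 kb); `ter_edge_kb = 2600` between 2499 and 2672 kb. An edge placed
below 851 kb would be self-contradictory: the 851-kb locus would then be
generated as an arm locus with a final position of ≈ 0.22, inside the
region classifier's own Ori tolerance (0.2 ± 0.06), so the generating
labels and the classifier could never agree there. A per-locus
`pole_shift` hook exists (default 0) for loci reported slightly poleward
of the region consensus; it is deliberately unused by the defaults.

## Numerical and design choices in the pipeline

* **Orientation** uses the mean of the reference-channel foci; cells whose
  reference mean lies within 0.05 relative units of mid-cell are flagged
  ambiguous and excluded (threshold configurable, provenance recorded).
  This matters for large cells, where a terminus reference approaches
  mid-cell: orientation there rests on the minority of large cells whose
  reference has not yet relocated.
* **Bin occupancy**: fractions from size bins with fewer than 20 cells are
  flagged rather than silently dropped.
* **Interfocal pairing**: 1-vs-1 focus cells by default; 2-vs-2 cells use
  minimal-sum matching when `pairing = "matched"`. The colocalization
  threshold defaults to 0.3 µm = `d_res_um`, since "colocalized" is
  otherwise undefined.
* **Two-focus ranking**: per-cell pole-proximal/pole-distal ranking before
  pooling, so the two reported series are order statistics.
* **Replisome analyses run unoriented** (positions also folded about
  mid-cell): replisome experiments carry no terminus reference channel.
* **The switching-rule profile** reports one-focus medians only when
  one-focus cells are a *strict* majority of the bin; at exactly 50% the
  two-focus branch fires.
* **Ter separation is a jump**, by construction (a fixed offset appearing
  late in the cycle); the continuity of trajectories is therefore asserted
  for all non-Ter loci and unflagged Ter loci only.
* **C-period estimation** from segregation-curve crossings corrects each
  crossing age for the optical resolution lag
  $d_{\mathrm{res}} \cdot \mathrm{seg\_dur} / \Delta(x, L^*)$, where
  $\Delta$ is the copy separation at the crossing size: terminus-ward
  loci separate more slowly, so their apparent crossings are delayed more,
  and the uncorrected fit overestimates C by ~15%.

## RNG discipline

One master seed per simulation; per-cell substreams are derived from it by
cell index, and each cell's draws happen in a fixed order (age, newborn
length, polarity, Ter flag, then per-channel draws). Consequently adding
or removing a channel never perturbs other cells' draws, and identical
configurations give byte-identical output tables.

## What the generator emulates — and what it does not

The simulator emulates steady-state snapshot data: per-cell lengths, foci
per channel, localization noise, missed detections, sub-resolution merging
and hidden polarity. It does **not** emulate: 2-D/3-D geometry or nucleoid
shape, cell curvature or segmentation error, lineage correlations between
related cells, fork-trap or dimer-resolution mechanics, ParA/ParB dynamics
(the `par_null` mode is a phenomenological endpoint), anucleate-cell
formation, or photophysics beyond a flat detection probability (no
bleaching, no intensity information). Tests passing on synthetic
populations therefore validate the pipeline's statistics and the model's
internal consistency on idealized data; they do not establish that real
segmentation output obeys the same error model.

A known artifact of the linear position map plus hard optical merging: arm
loci with offsets ≈ 2100–2600 kb have final copy separations below the
merge distance at realistic cell sizes, so they behave "Ter-like" in focus
counts even though they are generated as arm loci. The real system's
near-dif arm markers do resolve; a soft merge model or a steeper position
map near the Ter edge would remove the artifact at the cost of parameters
the available summary statistics cannot constrain.

## Problem sizes used by the test-suite and acceptance runs

Population statistics are reproduced at n = 5000 cells per condition
(binomial SE ≤ 0.7 percentage points for the fractions of interest);
parameter-recovery properties (C period, size-trend monotonicity) use
n = 20 000 cells; the region classifier is exercised on all 20 panel loci
at n = 5000. Each simulation of this size completes in seconds.

## Reproducing the headline numbers

```r
cfg <- sim_config("citrate", 5000, seed = 1,
                  channels = c(ori = "82-R", ter = "2,957-R",
                               ref = "3,028-R", rep = "REPLISOME"))
tab <- sample_population(cfg)
cf  <- count_foci(tab, "ori")
mean(cf$n_foci[!cf$excluded] == 2L)            # ~0.92
replisome_summary(tab, "rep")$frac_one_among_positive  # ~0.92
ot  <- orient(tab, "ref")
position_summary(ot, "ori")                    # large-cell medians ~0.2/0.8
```

`scripts/acceptance.R --seed <int> --out <path>` recomputes all headline
statistics from scratch and writes them as JSON.
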