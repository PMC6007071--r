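---
title: "Dynamics of a single-molecule phosphorylation switch and its oscillatory reductions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics of a single-molecule phosphorylation switch and its oscillatory reductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model family

`phosswitch` models a single molecule with two phosphosites. Each site is
either unmodified (`O`) or phosphorylated (`P`), so the molecule adopts four
conformations: `OO`, `OP`, `PO` and `PP`. The two fully modified forms are
catalytically active and antagonistic: `PP` acts as a kinase, driving every
phosphorylation step, and `OO` acts as a phosphatase, driving every
dephosphorylation step. Every directed conversion between conformations also
has a slow spontaneous (uncatalysed) variant, giving 16 elementary reactions:
4 catalytic phosphorylations (`p0..p3`, catalyst `PP`), 4 catalytic
dephosphorylations (`d0..d3`, catalyst `OO`), and their spontaneous siblings
(`bp0..bp3`, `bd0..bd3`).

All phosphorylation rates scale with the phosphate-donor level `nt` (think
NTP) and all dephosphorylation rates with the acceptor level `nd` (NDP/NMP).
`nd` is held at 2 AU; `nt` is the bifurcation parameter. With mass action and
the conserved total `tot = OO + OP + PO + PP`, the `OP` equation is
eliminated algebraically and the dynamics integrated in the reduced state
`(OO, PP, PO)`:

$$
\begin{aligned}
\dot{OO} &= -(p_0{+}p_1)\,nt\,PP\,OO + (d_0\,OP + d_1\,PO)\,nd\,OO
           -(bp_0{+}bp_1)\,nt\,OO + (bd_0\,OP + bd_1\,PO)\,nd\\
\dot{PP} &= (p_3\,OP + p_2\,PO)\,nt\,PP - (d_2{+}d_3)\,nd\,OO\,PP
           +(bp_3\,OP + bp_2\,PO)\,nt - (bd_2{+}bd_3)\,nd\,PP\\
\dot{PO} &= p_1\,nt\,PP\,OO - p_2\,nt\,PP\,PO + d_2\,nd\,OO\,PP
           - d_1\,nd\,OO\,PO + bp_1\,nt\,OO - bp_2\,nt\,PO
           + bd_2\,nd\,PP - bd_1\,nd\,PO
\end{aligned}
$$

with $OP = tot - OO - PP - PO$. A *topology* is the subset of the 16
reactions that is active; deactivating a reaction is identical to setting its
rate to zero. The named presets use the standard "dummy" rates — every active
catalytic rate 1 AU, every active spontaneous rate 0.05 AU, `tot = 4`,
`nd = 2`:

* **TI** — all 16 reactions; the two-intermediate toggle switch.
* **AM** — the approximate-majority restriction: the `PO` routes are
  removed, so with `PO(0) = 0` the system is the classical three-state
  consensus switch. It is implemented as a TI topology restriction (one code
  path); the trajectory equivalence is a test, not an assumption.
* **BP** ("broken paths") — TI minus the `PO -> PP` path (`p2`, `bp2`) and
  the `OP -> OO` path (`d0`, `bd0`): bistability is lost, a small
  oscillatory window appears at the inflection of the remaining sigmoid
  response.
* **BD1** — BP minus the spontaneous `PO -> OO` reaction (`bd1`): a robust
  relaxation oscillator over a wide `nt` range.
* **CO** / **SO** — minimal four-reaction oscillators (`{p0, p3, d1, bd2}`
  and `{p0, d1, bp3, bd2}`), with the `OP -> PP` step catalytic (CO) or
  spontaneous (SO).

```{r}
library(phosswitch)
preset("BD1")
autoplot(simulate_timecourse(preset("BD1"), init = c(OO = 2.1, PP = 1.9),
                             nt = 4, t_end = 200))
```

## Numerical treatment

**Time integration.** Trajectories are integrated with `deSolve::lsoda`
through a compiled derivative routine, at relative tolerance `1e-8` and
absolute tolerance `1e-10`; relaxation cycles have fast switching phases that
need a stiff-capable method.

**Species without additive inflow.** In several reduced topologies a
catalytic form has *only self-proportional inflow*: `OO` when `bd0 = bd1 = 0`
(BD1, CO, SO), `PP` when `bp2 = bp3 = 0` (CO). During a relaxation cycle such
a species decays multiplicatively for most of the period; its true minimum
lies far below any usable absolute tolerance (at `nt = 10` the `OO` minimum
of BD1 is around `1e-130`, and it shrinks further with `nt`). In linear
coordinates a solver either fails outright or — worse — its tolerance floor
acts as a small artificial inflow that changes the dynamics. The package
therefore integrates such species in log coordinates, where the slope is a
plain polynomial in the other species and `exp()` underflows to zero
harmlessly; a multiplicative species started at exactly zero is pinned there,
which is what exact dynamics does. This choice is load-bearing: it is what
makes the high-`nt` behaviour of the oscillators (cycle death by collapse of
`OO`) computable at all, and it is cross-checked in the tests against an
independent plain-R derivative route.

**Steady states.** All steady states on the conservation simplex are located
by damped Newton iteration from a regular barycentric grid (step `tot/4`, 35
starts including the vertices) plus continuation seeds from neighbouring
`nt` values during sweeps. The Jacobian is analytic (the system is
polynomial); a central finite-difference Jacobian is kept as a cross-check
route. Roots are deduplicated at radius `1e-6` (max norm), roots with any
component below `-1e-8` are discarded as nonphysical, and stability is read
from the eigenvalue real parts of the reduced Jacobian with a marginal band
of `1e-6`. The band is wider than machine precision on purpose: CO and SO
possess a *structural equilibrium continuum* (every state with
`PP = PO = 0` is an equilibrium at every `nt`), and Newton lands on points
just off that line whose leading eigenvalue is a numerical perturbation of
the exact zero along the continuum. Those points must classify as marginal,
not stable; genuine isolated states near our bisection brackets have leading
eigenvalues orders of magnitude outside the band. For topologies in which
`PO` is structurally frozen (AM), the search and the stability analysis run
on the two-dimensional `(OO, PP)` slice.

**Limit cycles.** A sustained cycle is accepted when, in an analysis window
after a transient (default: cut at `t = 1000` AU, window 1000 AU), the `PP`
series shows peak-to-peak amplitude above `1e-3 * tot`, at least three peaks
of that prominence, regular inter-peak intervals (coefficient of variation
at most 0.05), and a non-decaying envelope (late-window amplitude at least
90% of the early-window one). `PP` is the reference species because it stays
active in every oscillatory preset; the period is the mean inter-peak
interval, with peak times refined by local parabolic interpolation. If the
window is too short for three peaks or the intervals have not settled, both
transient and window are doubled, up to three times, before the point is
declared inconclusive. The amplitude threshold and the decay guard are this
package's operational definition of "sustained oscillation"; no universal
criterion exists, and near a supercritical Hopf point any such definition is
visible in the reported boundary (see *Limitations*).

**Regime classification and boundaries.** A point is *bistable* when two or
more stable steady states coexist; otherwise *oscillatory* when a sustained
cycle is detected (with a small deterministic multi-start fallback when no
stable state exists); otherwise *absorbing* when the unique stable state
holds essentially the whole pool (within `1e-3` of `tot`, as in the AI
topology where `PO` is a sink); otherwise *monostable*. Sweeps run at step
0.05 — matching two-decimal reporting — with forward and backward
continuation so both stable branches are tracked across a hysteresis window,
and every boundary between differently classified grid points is refined by
bisection to a bracket of width 0.01. When oscillation persists at the top
of the scan range the range is extended by doubling (coarse step 0.5, then
bisection) until the regime closes or `nt = 100` is reached; an interval
still open at the cap is reported with an open-end flag.

```{r}
regime_table(c("AM", "TI", "BP"))
```

**Knockout scans.** A *path* is a directed conversion counted with both of
its mechanisms (catalytic plus spontaneous sibling). The scanner classifies
the 8 single-path removals of TI, the 16 pairwise removals (one
phosphorylation path with one dephosphorylation path — the only pairing
consistent with a 16-member family), and the 11 single-reaction removals
from BD1. The 16 pairs collapse to 8 orbits of size 2 under the site-swap
automorphism (relabelling of the two phosphosites: `OP <-> PO`, indices
`0 <-> 1`, `2 <-> 3` in every reaction family), which leaves `nt` and `nd`
untouched and is validated by a trajectory-equivalence test before the orbit
reduction is trusted. Orbit representatives are the lexicographically
smallest active sets; each orbit is classified once. The full phospho-swap
(`O <-> P` on both sites, exchanging the roles of `nt` and `nd`) is also
implemented and used for mirror-property tests only: it does *not* preserve
the `nt` scan and therefore cannot reduce the pairwise family.

## Design choices made where the design was open

* **Analytic Jacobian by default.** The system is polynomial, so exact
  derivatives are cheap; finite differences remain available
  (`jacobian = "fd"`) and the two routes are compared in tests.
* **Windows and transients.** Periods in this family are of order 10–100 AU
  over the standard scan ranges, so a 1000 AU window holds many cycles and a
  1000 AU transient cut suffices except near onset/offset points, where the
  doubling ladder takes over. Oscillation statistics are computed over whole
  periods (first to last detected peak).
* **Default oscillation start** `OO = 2.1, PP = 1.9, OP = PO = 0`: an
  asymmetric state off the invariant diagonal, the standard initial
  condition for oscillation runs in this family.
* **Extension policy.** BD1's oscillatory window closes only far beyond the
  standard `[0, 15]` range, so the boundary finder extends automatically;
  the same policy applied to CO shows its window closing near `nt ~ 27`,
  beyond the range usually scanned for it, while SO remains open at the
  `nt = 100` cap.
* **Reporting.** Boundaries are rounded to 2 decimals, TSV output uses 6
  significant digits, and negative integrator undershoots above `-1e-9` are
  clamped to zero in written output only — never inside the derivative
  evaluation.

## Problem sizes

The acceptance computations use the standard study conditions throughout:
scan step 0.05 with bisection to 0.01 over `[0, 10]` (AM, TI, BP and the
TI knockouts) or `[0, 15]` (BD1 and its knockouts, CO, SO, with automatic
extension), integration tolerances `1e-8`/`1e-10`, transient and window of
1000 AU each, and 100 random probes for the root-finder/long-integration
agreement property. The probe oracle integrates to `t = 3000` AU.

## Limitations

* Boundaries of oscillatory regimes located by an amplitude criterion are
  protocol-dependent near supercritical Hopf points: just above the Hopf the
  damping rate tends to zero (damping times of order `1e4` AU at the BD1
  offset), so any analysis with a short window reads slowly decaying ringing
  as sustained oscillation and widens the interval. This package's decay
  guard and long windows place onsets/offsets at the amplitude-threshold
  crossing adjacent to the Hopf; analyses with shorter horizons will report
  systematically wider windows, which should be kept in mind when comparing
  against other implementations of the same models.
* For topologies whose `OO` (or `PP`) has no additive inflow, the reported
  cycle death at high `nt` reflects the exact dynamics (irreversible
  collapse of the species), not a tolerance artifact; linear-coordinate
  integrators with an absolute-tolerance floor will instead report
  oscillations persisting to higher `nt`.
* Deterministic mass action only: no stochastic semantics, no delay terms,
  no Floquet analysis (limit-cycle stability is established empirically by
  multi-start convergence), and no two-parameter bifurcation surfaces
  (`nd` is fixed except in mirror-property tests).
* The equilibrium-continuum topologies (CO, SO) make "number of stable
  states" a fragile classifier at very small `nt`; the marginal band handles
  the cases that arise in the standard scans, but an exhaustive treatment of
  the continuum's transversal stability is out of scope.
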