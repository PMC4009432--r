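---
title: "Sparse distributed memory and the critical distance of recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse distributed memory and the critical distance of recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmemory)
```

## The model

Sparse Distributed Memory (Kanerva, 1988) stores n-bit items in a
random sample of the 2^n address space.  Only `H` *hard locations* are
instantiated (addresses drawn i.i.d. uniform over \{0,1\}^n), and each
owns one signed counter per dimension.  Writing a datum increments the
counter of every dimension holding a 1 and decrements every dimension
holding a 0, in **all** hard locations within an inclusive Hamming ball
of radius `r` around the write address (the *cell assembly*).  Reading
at a cue address sums the counters of the activated assembly per
dimension and takes the majority sign, flipping a fair coin on exact
ties.  Storage is autoassociative: an item is written at the address
equal to itself.

The access radius is chosen so that an operation activates a fixed
fraction of the sample, conventionally 1/1000 (roughly
`n/2 - 3*sqrt(n/4)`).  The exact binomial tail gives `r = 451` for
`n = 1000` and `r = 103` for `n = 256`:

```{r radii}
select_access_radius(1000, 1e-3)
select_access_radius(256, 1e-3)
```

Because a noisy cue shares part of its assembly with the stored target,
a read output is usually closer to the target than the cue was, and
iterating the read converges onto the stored item — up to a *critical
distance* beyond which iteration diverges instead.  This
convergence/divergence boundary is the model's analogue of the
tip-of-the-tongue state, and its location as a function of memory load
`s` (saturation) and target rehearsal count `w` is the quantity this
package computes, both analytically and by simulation.

## The analytic layer

For a cue at distance `d` from a target written `w` times in a memory
holding `s` items, with `h` locations activated per operation:

* `phi(d)` — expected number of hard locations shared by the cue's and
  the target's assemblies;
* `theta(d) = s*h^2/H - w*phi(d)` — expected number of *random* stored
  bits summed per dimension during the read;
* the per-dimension counter sum is `w*phi(d)` target votes plus a
  `Binomial(theta, 1/2)` noise sum, so the per-bit error probability is
  `P(wrong) = 1/2[(1 - alpha) + beta]` with
  `alpha = P(X < s*h^2/(2H))`, `beta = P(X < s*h^2/(2H) - w*phi(d))`,
  or in the normal approximation `P(wrong) = 1 - Phi(w*phi(d)/sqrt(theta))`;
* the critical distance solves `n*P(wrong) = d`, located on the integer
  grid by minimizing `f~(d) = (P(wrong) - d/n)^2`.

### Two overlap normalizations

The geometric intersection probability is exact and fully determined by
the model: a uniform point decomposes its distances to two centers `d`
apart as `k + j` and `(d - k) + j` with `k ~ Bin(d, 1/2)`,
`j ~ Bin(n - d, 1/2)`, giving the double binomial sum implemented (in
log space) by `shared_circle_count()`.  We validate it two independent
ways: exhaustive enumeration of all 2^16 points at `n = 16`, and Monte
Carlo sampling at `n = 1000`.

For the classical geometry (`n = 1000`, `r = 451`, `H = 10^6`) the raw
expected overlap at `d = 200` is 103.5, because the radius-451 ball
actually contains 1071.85 locations on average — not 1000.  Kanerva's
published overlap tables are instead stated on the scale of a nominal
1000-location assembly, i.e. normalized by the conditional overlap
fraction: `phi = h * P(both) / P(one)`.  `shared_assembly_count()`
implements that normalization and reproduces the table values exactly:

```{r overlap}
shared_circle_count(1000, 451, 1e6, c(200, 209))    # raw expectation
shared_assembly_count(1000, 451, 1000, c(200, 209)) # assembly scale
```

The theory layer uses the assembly normalization with the nominal `h`
carried in `theory_params()`; when `h` is left at its default (the
unconditional expectation `H * P(one)`), the two definitions coincide.
This choice is what makes the classical worked example come out
exactly:

```{r worked}
cp <- theory_params(1000, 1e6, 451, s = 1e4, w = 1, h = 1000)
theta(cp, 200, phi = 97)            # 903*10 + 97*9 random bits
1 - p_wrong(cp, 200, phi = 97)      # per-bit correct probability
f_tilde(cp, 209, phi = 87)          # objective at d = 209
```

### Numerical choices

* Binomial and normal tails come from `pbinom()`/`pnorm()` with
  `log.p = TRUE` where underflow threatens; the overlap sum is a
  log-sum-exp over at most `d + 1` terms, accurate for `n` well beyond
  10^4.
* The exact `p_wrong` uses `round(theta)` Bernoulli trials (theta is
  generally non-integer) and counts half of any boundary point mass as
  wrong, matching the read operation's fair tie-break.  Exact and
  normal methods agree within 0.01 for `theta >= 1000`.
* `f~` vanishes at *every* fixed point of `n*P(wrong) = d`, including
  the trivial one at the bottom of the convergent basin (`d` small,
  `P(wrong)` essentially 0), so a global argmin is not meaningful.
  `critical_distance()` therefore locates the divergence onset — the
  first sign change of `g(d) = n*P(wrong) - d` from negative to
  positive — and minimizes `f~` there.  Because `phi(d)` is constant on
  odd/even parity plateaus, `g` zigzags with period 2 near the onset,
  and the integer minimizer may sit one step outside the strict
  sign-change pair; the search window is widened by one plateau on each
  side.  Ties break toward the smaller distance.
* With the analytic overlap the classical configuration puts the onset
  at `d* = 222` (bracket 220–221).  The historically quoted 209 rests
  on interpolated table values and on rounding the per-bit probability
  to whole percentages before multiplying by `n`; the package reports
  the profile, the bracket and the argmin rather than forcing
  agreement, and reproduces the published objective value at 209 when
  the table overlaps (97, 87) are supplied via `phi` overrides.

## The simulation layer

`run_band_cell()` reproduces the heat-map procedure at one `(s, w)`
load: instantiate a store, write the target `w` times plus `s` uniform
random items once each (all autoassociatively), probe
`cues_per_distance` cues at every grid distance with
`iterative_read()`, and summarize:

* **green** — first probe distance with any failure to reach the exact
  target;
* **red** — last probe distance with any exact convergence;
* **blue** — empirical critical distance: first positive distance where
  the mean final distance is at least the cue distance (a linear
  interpolation of the crossing is reported alongside).

Convergence of an iterated read is declared when an output equals its
input (an observable fixed point — at the target this coincides with
exact retrieval); divergence when successive iterates jump by at least
`n/2 - 2*sqrt(n/4)` bits, i.e. the iterate has relocated to an
essentially random point.  The model itself prescribes no operational
divergence rule; this one is scale-free and conservative.

### Scale

The default benchmark is `n = 256`, `H = 10^4`, activation fraction
10^-3, 20 cues per distance, probe step 4, iteration budget 6 — a
configuration whose full band takes seconds per `(s, w)` cell on one
CPU while preserving the full-scale phenomenology: rehearsal (`w` up)
widens the band, saturation (`s` up) shrinks it, and the gain from one
read to six dwarfs the gain from six to forty.  The full-scale
geometry (`n = 1000`, `H = 10^6`) is a configuration choice, not a
code change, but a single full-scale heat map demands on the order of
10^15 bit-compares and is out of desk reach.

One desk-scale caveat: with ~10 locations per assembly, a single read
is very noisy, and iteration occasionally amplifies an early mistake
into a full escape.  The *mean-based* blue line can therefore sit
slightly lower with six reads than with one, even though the *reach of
exact convergence* (red line) grows sharply — at full scale, with
~1000-location assemblies, both move together.  Tests of the
iteration-budget effect are phrased accordingly.

### What the generator does and does not emulate

Stored items are i.i.d. uniform bitstrings written exactly once, with
one designated target written `w` times — precisely the regime of the
analytic theory.  Real memoranda are correlated, revisit rates are
heterogeneous, and hard locations need not be uniform; none of that is
modelled, so passing tests validate the model's internal consistency
and its published numbers, not its fit to behavioral data.

## Reproducibility

Every stochastic step draws from a stream derived from one root seed
plus purpose labels (`stream_seed(seed, "cues", s, w, d, i)` and so
on), so any experiment cell can be regenerated in isolation, sweeps are
bit-exact reproducible, and trajectories at different iteration budgets
share their common prefix bit-for-bit.  Read tie-breaks use a dedicated
stream so that write reproducibility is decoupled from read
reproducibility.

## Limitations

* Counters are unbounded signed integers (the binary container refuses
  to serialize magnitudes beyond 32 bits); no forgetting or decay.
* Activation is the pure inclusive Hamming ball — no
  selected-coordinate or jittered designs.
* Heteroassociative sequence storage is out of scope; writes are
  autoassociative unless an explicit `datum` is passed.
* The store lives in dense matrices, which is the right trade at desk
  scale (`H*n` up to ~10^7) but would need bit-packing and compiled
  kernels at the full 10^6-location scale.
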