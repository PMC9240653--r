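---
title: "Simulating multi-person adaptive metronomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-person adaptive metronomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemsim)
```

## The model

An adaptive metronome mimics, in a controlled way, the timing accommodation
another human might offer during joint tapping. Tones are nominally separated
by an inter-onset interval (IOI, 500 ms by default), and each upcoming tone
is shifted by a fraction $\alpha$ of the current tap asynchrony:

$$ t^{met}_{n+1} = t^{met}_n + \mathrm{IOI} + \alpha \cdot \overline{async}_n, $$

where a tapper's asynchrony is its tap time minus the tone time, and
$\overline{async}_n$ averages over the tappers in the group (group size 1-4).
$\alpha = 0$ is a rigid, conventional metronome; $\alpha = 1$ moves the next
tone by the full mean asynchrony. Taps are attributed to a tone if they land
within half an IOI of it; we close that window half-open on the right,
$[t - \mathrm{IOI}/2,\ t + \mathrm{IOI}/2)$, an explicit convention where the
verbal "plus or minus half the IOI" rule leaves the boundary ambiguous. A
missed tap contributes an asynchrony of 0 to the adaptation — the next tone
then falls at the default IOI — but is stored as missing so that the analysis
side can exclude rather than zero-fill it (zero-filling would bias SD
estimates toward 0).

The first two tones establish the tempo and are always scheduled at the
nominal IOI; tone 3 is the first that can be adapted, driven by window-2
asynchronies. Participants (and, by default, the virtual tappers) join at
tone 3, so in practice the first two inter-tone intervals are exactly the
IOI. Times are real-valued milliseconds inside the engine; rounding to
integer ms happens only at serialization. At extreme parameter combinations
($\alpha \cdot async \approx -\mathrm{IOI}/2$) the next tone can be scheduled
at or before the current window's close; the engine allows this and warns
rather than clamping, since the device's behaviour there is unspecified.

## Virtual tappers

Human participants are stood in for by a Wing–Kristofferson two-level timing
generator with linear phase correction:

$$ t^{tap}_{n+1} = t^{tap}_n + \mathrm{IOI} - \beta\, a_n + T_n + (M_{n+1} - M_n), $$

with timekeeper noise $T \sim \mathcal N(0, \sigma_T^2)$, motor delays
$M \sim \mathcal N(0, \sigma_M^2)$ (whose differencing gives the classic
MA(1) signature of inter-tap intervals), and phase-correction gain $\beta$ —
the tapper-side analogue of $\alpha$. Each tapper draws from its own seeded
stream, so trials are bit-reproducible and tappers independent. Misses occur
with probability `p_miss` per window; a missed tap stays covert — the tapper
keeps cycling and corrects from the asynchrony its unregistered tap would
have had, as humans do.

Coupled to the metronome, a single tapper's asynchrony follows
$a_{n+1} = \varphi a_n + T_n + M_{n+1} - M_n$ with
$\varphi = 1 - \alpha - \beta$: an ARMA(1,1) with stationary variance

$$ \mathrm{Var}(a) = \frac{\sigma_T^2 + 2(1-\varphi)\sigma_M^2}{1-\varphi^2},
   \qquad |\varphi| < 1. $$

`stationary_async_sd()` implements this closed form. It was derived from the
recursion above (the innovation $T_n + M_{n+1} - M_n$ has variance
$\sigma_T^2 + 2\sigma_M^2$ and covariance $-\sigma_M^2$ with $a_n$ through
the shared $M_n$) and is validated in the test-suite against $10^5$-window
simulations over a grid of $(\alpha, \beta)$, using batch-means Monte-Carlo
standard errors because the series is autocorrelated. The closed form holds
for the default `period_mode = "nominal"`, in which the timekeeper targets
the nominal IOI throughout; the alternative `"tracking"` mode (the
timekeeper targets the last observed tone interval) is provided for
exploring tempo-following behaviour but voids the oracle — with full
tracking and no correction the characteristic equation acquires a unit root
and asynchronies persist instead of decaying.

The stationary SD is U-shaped in $\alpha$ for moderate $\beta$: with
$\beta = 0.2$, $\sigma_T = \sigma_M = 10$ ms it falls from 19.7 ms at
$\alpha = 0$ to 16.2 ms at $\alpha = 0.35$ and rises again toward
$\alpha = 1$. This reproduces, qualitatively, the human finding that
moderate adaptivity improves synchronization while excessive adaptivity
returns it to baseline or worse. No claim is made that the default
$\beta$ or noise magnitudes are calibrated to human values — the source
experiments model the metronome, not the participant — so green simulation
tests establish the direction of adaptivity effects, not their printed
millisecond sizes, which depend on human parameters we do not estimate.

## What the generator does and does not emulate

Emulated: window-based tap registration, miss handling, group-mean
adaptation, randomized adaptivity order across rounds, per-trial seed
derivation from one master seed, and the published designs — 10 rounds at
each $\alpha \in \{0, 0.25, 0.5, 0.75, 1\}$ with 25 tones per round at IOI
500 ms for single tappers; 6 rounds at each
$\alpha \in \{0, 0.35, 0.7, 1\}$ for groups of four. Group rounds are stated
only as "approximately 30 s", so the presets use 60 tones (30 s at 500 ms);
this is configurable. Practice rounds are available behind a flag, always at
$\alpha = 0$, and excluded from analysis outputs.

Not emulated: audition (feedback conditions are metadata tags; if desired,
they can be encoded as tapper-parameter presets, e.g. lower $\beta$ and
higher noise for "no feedback"), inter-trial learning, tempo drift beyond
`tracking` mode, multi-tap debouncing within a window, and survey-taking
behaviour.

## Numerical and design choices

* **Missing-tap sentinel.** The 12-byte packet stores the tone onset as an
  unsigned little-endian 32-bit integer and four signed 16-bit relative tap
  times. The original firmware's missing-tap encoding is not documented; we
  declare −32768 (INT16_MIN, outside any legal half-IOI window) and
  little-endian order (the AVR convention), and state rather than infer
  both.
* **Population SDs.** The defining formulas for the synchrony metrics divide
  by the count, not count − 1, so all metric SDs are population SDs by
  default; `sample = TRUE` is available. Rating z-scores, by contrast, use
  the sample SD, matching the common implementation of the normalization
  step.
* **Misses in metrics.** Metrics exclude missing taps (the engine
  zero-fills them only for adaptation). A window in which nobody tapped is
  excluded from the group series and flagged.
* **Rank ties.** Tappers are ranked by the absolute individual-minus-group
  SD asynchrony difference, rank 1 smallest; exact ties break by tapper
  index for determinism.
* **Cleaning thresholds.** The published rules are asymmetric — participants
  are dropped at ≥ 30% misses overall, individual rounds at > 30% — and we
  preserve that asymmetry rather than harmonize it. Whether the two lead-in
  tones count toward the "required" taps is unstated; by default all windows
  count, with `exclude_lead_in = TRUE` to discount them.
* **Degenerate z-scores.** A participant × scale cell with zero variance
  (or a single trial) maps to z = 0 with a warning.
* **Enjoyment scoring.** Scores are fixed-loading weighted sums of z-scored
  items (groove, synchrony with the metronome and — in groups — with the
  others, liking, and difficulty negatively; felt influence is excluded for
  loading below |0.3|). This is a documented approximation: the original
  scores came from a fitted maximum-likelihood factor model, which cannot be
  reproduced without the raw human data, so exact score equality is out of
  reach by construction. User-supplied loadings are accepted.
* **Seeds.** Per-trial and per-tapper streams derive from the master seed by
  a MINSTD-style 32-bit mix, keeping every derived seed below $2^{31}$.
* **Configs.** Design configuration files are JSON (not YAML) to stay within
  the guaranteed dependency set.

## A worked run

```{r, eval = FALSE}
dir <- tempfile()
gem_simulate(dir, seed = 7, preset = "exp3")   # 24 group trials to .gem + CSV
res <- gem_analyze(dir)
res$summary$mean_group_sd_async_by_alpha
plot_sd_by_alpha(res$metrics)
```

## Known limitations

Tapper parameters are free simulator inputs, not estimates from human data;
the package deliberately stops at exporting tidy metric tables, leaving
mixed-effects models, ANOVAs, and factor-model estimation to standard tools.
The binary format choices (sentinel, endianness) are declared conventions
that a real device log may or may not share; the CSV path accepts any data
in the documented schema.
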