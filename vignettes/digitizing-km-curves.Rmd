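---
title: "Digitizing Kaplan-Meier curves from plot images"
author: "kmdigitize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing Kaplan-Meier curves from plot images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmdigitize)
```

## The problem

Health-economic models and meta-analyses routinely need survival
probabilities from trials whose individual patient data (IPD) are not
available. What is available is the published Kaplan-Meier (KM) plot: a
non-increasing step function of survival probability against time,
usually accompanied by a number-at-risk table. `kmdigitize` turns a
raster image of such a plot (PNG or JPEG) into a `(time, survival,
curve)` table, and optionally reconstructs pseudo-IPD whose refitted KM
curve matches the digitized one and whose at-risk counts match the
published table exactly.

## The digitization pipeline

The pipeline runs seven stages, each exposed as an exported function so
any stage can be inspected or replaced:

1. **`loadImage`** decodes the image and converts every pixel to
   hue-saturation-lightness (bi-hexcone HSL: $L = (\max + \min)/2$, hue
   stored as a fraction of a turn in $[0, 1)$). Lightness is what makes
   the rest simple: white background sits at $L \ge 0.8$, black axes and
   text at $L \le 0.2$, and visibly coloured curve pixels in between.
2. **`detectAxes`** counts dark pixels ($L \le 0.2$) along every row and
   column; the y axis is the column with the most dark pixels (leftmost
   on ties, so the left edge of a framed box wins), the x axis the row
   with the most (bottommost on ties). A candidate must cover at least
   half its dimension, which rejects dense text rows. The plot region is
   the rectangle right of and above the axis lines, inset by 4 px:
   JPEG compression rings around a dark line for a few pixels, and those
   ring pixels must not enter the curve mask.
3. **`removeBackground`** keeps pixels with $L <$ 0.8 inside the region;
   **`removeText`** (optional) groups remaining dark pixels into
   connected components, shows each to a character recognizer, and
   deletes purely alphabetic words of length $\ge 2$ recognized with
   confidence $\ge 60$. The recognizer is pluggable; the default shells
   out to a `tesseract` binary when one is installed, and the stage is
   an identity when OCR is disabled. Because an OCR engine cannot be
   assumed present, the pipeline default is `ocr_enabled = FALSE`:
   enabling OCR without an engine is a configuration error, not a
   silent no-op.
4. **`clusterPixels`** separates curves by colour: each pixel becomes
   $(\mathrm{hue} \cdot h_b,\ \mathrm{sat},\ \mathrm{light} \cdot l_b)$
   with boosts $h_b = 2$, $l_b = 1$, partitioned by PAM k-medoids with
   $k$ = the user-declared number of curves. Hue is circular; a
   saturated red straddles the wrap point once compression noise is
   added, so the hue axis is first cut at the centre of the largest
   empty arc of the observed hue histogram. Masks beyond 3000 pixels
   use `cluster::clara` (PAM on subsamples, seeded) since full PAM is
   quadratic; pixels at $L \le 0.2$ can be dropped first
   (`drop_dark_censor_marks`) to discard black censoring ticks.
5. **`knnScore` / `tracePath`** reduce each cluster to a single-pixel
   monotone staircase. The coherence score of a pixel $p$ is
   $\sum_{i=1}^{k} \mathrm{comp}(p, n_i)/d(p, n_i)^2$ over its $k = 20$
   nearest labelled pixels, $\mathrm{comp} = +1$ for a shared label and
   $-1$ otherwise. The trace starts at the curve's left-most, then
   top-most coherent pixel (a decreasing curve departs from its
   top-left origin; mislabelled compression halos accumulate at later
   times and would capture a purely top-most start) and repeatedly steps
   right or down, letting the score arbitrate when both moves stay in
   the cluster. When neither forward pixel exists the gap is bridged:
   the trace scans rightward for the nearest column holding a coherent
   (positive-score) cluster pixel at the same or lower height, filling
   horizontally, then downward within the column. The scan horizon
   defaults to the full region width because two KM curves at the same
   quantized survival level coincide exactly and the curve drawn on top
   owns all shared pixels -- hidden spans routinely exceed any small
   horizon, and truncating there would charge the whole remaining tail
   as error under the evaluation's exhaustion rule.
6. **`calibrateAxes`** finds tick marks as short dark runs just outside
   each axis (15 px band, runs of $\ge 3$ px). The extreme ticks anchor
   the user-declared (start, end); with every tick detected this equals
   increment over adjacent-tick spacing, and it stays correct when
   interior ticks are missed. Declared ranges are authoritative; OCR,
   when available, only verifies the labels and warns on mismatch. With
   fewer than two ticks the plot region's extent is mapped onto the
   declared range (warned).
7. **`mapToUnits` / `aggregateCurves`** collapse the staircase to the
   bottom-most pixel per column (the post-drop level -- KM curves are
   right-continuous), convert to units, compress equal consecutive
   survival values to step changes, and emit the long table
   `id, time, St, curve`. Times within one pixel-width of zero snap
   to 0.

## The simulation study

`runSimulationStudy()` rebuilds the validation experiment end to end.
Cohorts draw event times from Exp(rate 0.01) and, when censoring is on,
independent censoring times from Exp(rate 0.005); the observed time is
the minimum. Subjects are assigned to 1-3 arms uniformly at random,
which deliberately produces heavily overlapping curves. The grid
crosses $N \in \{25, 50, 150, 250, 1000\}$, 1-3 curves per plot,
censoring on/off and two rendering styles: 60 plots, 120 curves.

Plots are rendered by a purpose-built deterministic rasterizer
(`renderKMPlot`) rather than an R graphics device: it gives pixel-exact
control of axis and tick geometry, has no font or device dependence,
and produces byte-reproducible JPEGs (quality 0.95). The plot region is
1600 x 1000 pixels. `style_a` is a base-graphics-like preset (white
background, 3 px lines); `style_b` a gray-panel preset (panel lightness
0.93 with white grid lines, 5 px lines). Censoring marks are vertical
ticks drawn in the curve's own colour, centred on the curve, as common
plotting engines do; they are the main source of difficulty in the
censored stratum, since a mark's below-curve half can momentarily pull
the trace downward. JPEG compression noise is left in deliberately --
thresholds downstream must absorb it, as they must for real published
images.

Accuracy is scored per curve at 100 time checkpoints spaced evenly from
0 to the true curve's maximum study time (its last knot, so a truncated
digitization is penalized). Both curves are evaluated with a
right-continuous step lookup plus an exhaustion rule: when every knot
of a curve lies at or below the checkpoint, its value is 0 (no
survivors beyond the digitized range). The per-plot RMSE is the mean of
its curve RMSEs. `blandAltman()` (mean difference $\pm 1.96$ SD) and
`kendallTau()` (tau-b, tie-corrected -- digitized step functions are
full of ties) support agreement analyses between two digitizations of
the same plot. Note that for two valid survival step functions the
paired series are both non-increasing, so tau near $-1$ cannot occur;
the tau-b computation itself is checked against brute-force pair
counting in the test suite.

What the generator does *not* emulate: anti-aliased or dashed lines,
confidence bands, legends and in-panel text, rotated or photographed
plots, and axis styles other than linear. Passing the study therefore
demonstrates correctness of the pipeline's geometry, clustering,
tracing and calibration under realistic compression noise and curve
overlap -- not robustness to every typographic habit found in journals.

## IPD reconstruction

Given the digitized table and a number-at-risk table,
`buildIntervalTable()` assigns digitized rows to risk intervals
(left-closed on boundaries, final interval closed at the last digitized
time). `reconstructIPD()` then solves, per interval, for integer event
and censoring counts: events at each digitized drop follow the rounded
product-limit inversion $d_i = \mathrm{round}(n_i (1 - s_i / S))$
against the running reconstructed level $S$; censorings are spread
evenly across the interval (and strictly inside it in time); the
censoring total is iterated until the count remaining at the next
boundary equals the published number *exactly* -- this is a hard
constraint, enforced by a final adjustment at the interval end, and an
infeasible table raises an error naming the interval. Subjects
remaining after the last digitized point are censored there, unless a
known total event count requires assigning them as terminal events.
`refitKM()` refits the records with the product-limit estimator; on
simulated round trips (cohort of 100+ subjects, rendered, digitized,
reconstructed) the refit stays within 0.02 of the digitized curve and
at-risk counts match exactly.

## Numerical choices and defaults

| Parameter | Default | Why |
|---|---|---|
| `bg_lightness_threshold` | 0.8 | white/gridline band of the lightness scale |
| `dark_threshold` | 0.2 | black/dark-gray band (axes, text, black marks) |
| `knn_k` | 20 | neighbourhood large enough to out-vote thin artifact strips |
| `hue_boost`, `light_boost` | 2, 1 | keeps hue dominant over saturation for curve separation |
| `gap_horizon_frac` | 1 | overlapping same-level curves hide one another for long spans |
| `region_inset` | 4 px | reach of JPEG ringing around a dark axis line |
| `ocr_confidence` | 60 | only confidently-read alphabetic words are deleted |
| `seed` | 42 | subsampled PAM is the pipeline's only stochastic step |

Ties in the knn neighbour ordering break lexicographically by
(col, row); ties between the right and down move break rightward (time
advances). Degenerate inputs fail loudly with classed errors
(`kmConfigError`, `kmAxesError`, `kmClusterError`, ...) carrying the
stage name and a remediation hint.

## Known limitations

Curves sharing one colour and hue cannot be separated (declared
impossible for a colour-based clusterer); dash patterns are not used.
Rotated or skewed scans defeat the row/column axis detection. Black
background grids merge with the axes and must be cleaned manually
before digitization. Log-scale or percent axes are expressed by
rescaling the declared ranges, not detected. The IPD heuristic requires
the risk table to cover time 0 and to be arithmetically consistent with
the digitized drops.

## Reproducing the study

```{r, eval = FALSE}
res <- runSimulationStudy(seed = 1)
mean(res$plots$rmse)                       # headline accuracy
aggregate(rmse ~ censoring, res$plots, mean)
```

A full 60-plot run takes a few minutes on one CPU. The repository's
`scripts/acceptance.R` wraps exactly this computation and writes the
headline mean RMSE as JSON.
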