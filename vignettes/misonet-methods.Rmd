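---
title: "MISO state-space effective connectivity for preictal iEEG: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MISO state-space effective connectivity for preictal iEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`misonet` estimates time-varying directed ("effective") connectivity from
multichannel intracranial EEG and scans the resulting graph-centrality
series for the network-state transitions that precede focal seizures.
This vignette is the package's own account of the science: the model, the
estimator, every tunable that matters, what the synthetic generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## The model and its estimator

Each channel $k$ is treated as the output of a linear time-invariant
multi-input single-output (MISO) state-space system driven by all other
channels:

$$\dot{x}_k = A_k x_k(t) + B_k Y(t), \qquad
  y_k(t) = C_k x_k(t) + e_k(t),$$

with an $m$-dimensional latent state $x_k$ and measurement noise $e_k$.
Because the state is latent, least squares cannot act on this form
directly. The package estimates instead a multi-input ARX predictor of
order $m$ — $m$ lags of the target and of every input channel — by
QR-factorized least squares, and realizes it in observer canonical form:
$A_k$ is the $m \times m$ companion matrix of the self-lag coefficients,
column $j$ of $B_k$ stacks input $j$'s lag coefficients, and
$C_k = (1, 0, \ldots, 0)$. This is linear in its parameters,
deterministic, and preserves the quantity of interest: the Euclidean
column norm $b_{kj} = \lVert b_{k,j}\rVert_2$, the influence of channel
$j$ on channel $k$. Inputs enter at lags $\ge 1$ (no feedthrough), so the
predictor is strictly causal.

One technical point matters in practice. After common average
referencing (CAR) the channels sum to zero at every sample, so the full
lag design — $m$ lags of all $N$ channels — is *exactly* collinear, with
an $m$-dimensional null space (one direction per lag). The least-squares
solution is then non-unique. When the deficiency is at most $m$ the
package returns the minimum-norm solution (truncated SVD), the unique
completion that treats all channels symmetrically; any larger deficiency
is an error. Users should know that the null-space component is genuinely
unidentifiable after CAR: the minimum-norm convention shifts every
channel's coefficients by a common per-lag constant, which can compress
or even invert *small* between-edge contrasts. On reference-free data
(such as the synthetic generator's output) the design is full rank and
plain QR applies; this is one of two reasons the synthetic pipeline runs
skip CAR (the other being that montage correction corrects an artifact
the generator does not produce).

### Epoching

The analysis window is 10 s advanced by 1 s over the 120 s before
seizure onset, giving 120 epochs. An epoch is labelled by its window
**end** time, so windows end at $-119, \ldots, 0$ s relative to onset and
no window leaks past onset; the recording must therefore cover 129 s
before onset. Fits use the first 80% (8 s) of each window; validation
uses the final 20% (2 s), samples never seen in fitting.

### Model validation

A fitted model is accepted only if its held-out residuals pass two tests
at the 95% level: *whiteness* (Ljung–Box portmanteau over 20 lags) and
*independence* of residuals from **past** input samples (maximum absolute
cross-correlation over lags 1–20 per input, referred to its Gaussian null
and Sidak-corrected for the number of lag-by-input comparisons). Two
choices deserve comment.

* The independence test is causal by default. iEEG channels form a
  feedback system — every channel drives every other, and CAR mixes them
  instantaneously — so residual–input correlation at zero and negative
  lags is *expected* for a correct model and would reject
  systematically. A `two_sided` option restores the symmetric test for
  open-loop data.
* The two p-values are Holm-adjusted as a family before the accept
  decision, so "accepted" has 5% size under the null. A naive AND of two
  5%-level tests would have a 9.7% false-rejection rate, which is not a
  "95% confidence" decision.

Rejected models contribute an all-zero row to that epoch's connectivity
matrix and a bit in a rejection mask; masked rows are excluded from the
pruning pool so rejections do not deflate the threshold. Note a
consequence visible in the synthetic runs: windows that straddle a true
regime change are nonstationary, their models fail validation more
often, and the centrality series can *dip* just after a transition
before recovering.

### Order selection

The state dimension $m$ is shared across all channels and epochs
(comparability), selected by minimizing the average Akaike Information
Criterion $n\,\ln(\text{mse}) + 2\,(\text{parameters})$ across a
subsample of epochs (default: every 10th) over a grid (default 1–8).
Orders at which every fit fails validation are excluded.

## Networks, pruning, centrality

Entry $(k, j)$ of an epoch's connectivity matrix is $b_{kj}$ (influence
$j \to k$); the matrix is non-symmetric with a zero diagonal. Matrices
are pruned by retaining entries **strictly above** the 95th percentile
(linear-interpolation definition) of the pooled off-diagonal entries —
by default pooled over all epochs of the run, with a precomputed
threshold accepted to emulate wider pooling. Pruned graphs are treated
as **binary**: only the existence of strong connections is analysed, not
their relative strength.

Degree centrality is total degree (in + out), the faithful reading of
"connections at a node" for an oriented graph; a single-direction variant
is available. Betweenness centrality is directed, unweighted and
unnormalized (raw shortest-path counts, fractional over tied shortest
paths), with unreachable pairs contributing zero. Composition measures
are computed per node and then averaged within a group: the intragroup
percentage of a node's incident edges, and the outgoing percentage of a
node's connections (zero-degree nodes are excluded from the average and
counted).

## Transition detection

The paper-derived rule: a state transition is the first epoch whose
group-mean centrality exceeds the preceding state's mean by more than
one of its standard deviations. The package implements this with an
expanding baseline (the whole preceding state, frozen at the detected
epoch) and two robustness options that default conservatively:

* `persist`: the number of consecutive exceedances required (1 by
  default, per the literal rule).
* minimum baseline lengths before each transition can fire (40 epochs
  for the first, 20 for the second).

The first transition is sought on the SOZ series; the second on the
pooled PSZ+NSZ series with the between-transition state as baseline. The
transition metric defaults to BC, which in large clinical montages is the
more robust choice; DC is selectable. **On the synthetic scenario the
package's own analyses use DC**: the planted SOZ is a 3-node clique, and
a clique has structurally zero betweenness (every pair is adjacent), so
BC carries no signal at that scale.

Transition times convert epoch indices by $t = -120 + i$ (window end
time). For locating a *step* change with a symmetric sliding window, the
ground-truth anchor is the epoch whose window centre crosses the step
(e.g. a step 40 s before onset maps to epoch 85); windows earlier than
that contain mostly pre-step data, and the exceedance rule typically
fires one to three epochs after the anchor, when the window is half
filled with post-step samples.

## The synthetic generator

The generator exists to make the whole pipeline verifiable against known
ground truth, not to claim a mechanism for preictal dynamics. It
simulates a piecewise-stationary vector autoregression (order 3 by
default) whose coupling matrix switches instantaneously at two planted
times, driven by Gaussian innovations mixed with spectrally-shaped
$1/f$ (pink) noise; 5 s of burn-in are discarded. Defaults, all
overridable, and why:

* **12 channels** (3 SOZ / 3 PSZ / 6 NSZ), **512 Hz**, **140 s** ending
  at onset — the smallest montage with meaningful groups that still
  supports the 129 s epoching requirement.
* **Cross-coupling acts at lag 1 only**, so an edge's coupling equals the
  norm the estimator reports; self-dynamics are a fixed stable AR(3)
  (0.30, −0.08, 0.02).
* **Background**: a dense weak floor (0.01) plus a sparse stable
  "backbone" — 3 strong edges (0.25) between non-SOZ channels and one
  afferent edge into the SOZ. Interictal iEEG networks are not flat;
  they show sparse persistent clusters, and without stable
  above-threshold edges the pruned baseline graphs consist entirely of
  estimation-noise flickers, which no 1-SD rule survives at 12 channels.
  The backbone avoids SOZ sources (and the SOZ→afferent-source couplings
  are zeroed) because a strong edge closing a cycle with the planted
  SOZ-outgoing couplings raises the process spectral radius — cycle gain
  enters as the cycle-length-th root — and would destabilize the
  recruitment phase.
* **Steps**: SOZ→SOZ couplings ×30 (to 0.30) at 40 s before onset;
  SOZ→PSZ/NSZ ×28 (to 0.28) at 10 s. These are "strong" on purpose: the
  10-s window smears a step over 10 epochs, and the detection rule can
  only fire once enough of the window is post-step; weaker steps are
  recovered, but with longer latency than a ±3-epoch localization
  budget. Any phase whose companion matrix would be unstable is rescaled
  toward stability and the factor recorded.
* **Pink fraction 0.05**: a linear time-invariant ARX cannot whiten
  heavy $1/f$ innovations, and the Ljung–Box validation (n ≈ 1000) is
  powerful — at a pink fraction of 0.1 about a third of correct-model
  fits fail whiteness, and the masking rule then degrades every
  downstream series. The default keeps a visible pink floor while
  leaving validation acceptance near its nominal level; raising it is a
  deliberate way to stress the validation machinery.
* The afferent (incoming) interictal SOZ edge makes the interictal SOZ
  connected but driven, so the outgoing-fraction series has a
  well-defined low starting point and the canonical composition pattern
  — intragroup SOZ percentage rising at the first transition and
  collapsing at the second, outgoing percentage rising across all three
  states — is reproducible at this scale.
* An optional 2 Hz sinusoidal **delta drive** on SOZ channels supports
  spectral-contrast checks.

What the generator does **not** emulate: seizure waveform morphology,
spikes or high-frequency oscillations, line-noise or movement artifacts,
nonstationary drift within a state, volume conduction, or a common
recording reference. Passing tests on this scenario therefore demonstrate
that the estimator, pruning, centrality and detection machinery recover
planted directed-network structure under realistic noise and epoching —
not that the method is validated on clinical recordings.

## Spectral and statistical components

Band powers integrate a Welch power spectral density (2 s Hann segments,
50% overlap) over delta (<4 Hz), theta (4–7), alpha (8–13), beta
(13–25) and gamma bands; gamma is defined here as 25–55 Hz, capped
below the 60 Hz notch region since its upper limit is conventionally
unstated. Log powers are base 10, and zero-power epochs are excluded
from log averages with a count. Group differences use the Kruskal–Wallis
test (tie-corrected, chi-square reference) with Dunn's post-hoc pairwise
z-tests on mean ranks; the pairwise family is Holm-adjusted by default
(Bonferroni and unadjusted variants are available) since the original
analysis does not name its correction.

## Numerical notes and degenerate inputs

* The 0.5–256 Hz "band-pass" at 512 Hz has its upper edge at Nyquist,
  where a band edge is ill-posed; the filter degrades to the 10th-order
  high-pass branch and says so. High-order Butterworth filters at very
  low normalized cutoffs are numerically unstable in expanded
  transfer-function form, so filters are realized as cascades of
  bilinear-transformed second-order sections and applied
  forward–backward (zero phase — lag asymmetries would masquerade as
  directed influence).
* Degenerate validation inputs (zero-variance residuals) are rejected
  with an explicit flag rather than passed.
* A constant detection baseline has SD 0; any strict increase then
  triggers, which is documented behaviour.
* Ties in the top-fraction network are broken deterministically by
  (row, column) order and the count of ties at the cut is recorded.
* All simulations are seeded; identical configuration and seed give
  bit-identical output, including across the R session's RNG state
  (the generator draws its backbone in a restored-state local stream).

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen so the full suite completes comfortably on a single CPU: 200
random digraphs (n ≤ 8) against an exhaustive path-enumeration oracle;
a 10,000-entry pruning pool; 50 static recovery simulations (8 channels,
10 planted edges, 10 s; threshold pooled with 10 background matrices per
run, mirroring an interictal-dominated pool); 1000 calibration trials
for validation and for Kruskal–Wallis; 50 order-selection runs; and 100
end-to-end scenario runs (the acceptance script uses smaller counts of
the same computations). The known limitations are those of the scale:
3-node groups make betweenness degenerate, single-run pooling makes the
95th-percentile threshold sensitive to the strong-edge mass, and the
1-SD rule's false-alarm behaviour on 12-channel graphs requires the
persistence option that large clinical montages would not need.
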