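---
title: "Methods: point-process likelihood spaces for spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-process likelihood spaces for spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(likspace)
```

This vignette is the package's own account of the methods it implements: the
models and their assumptions, the parameters that matter, the numerical
conventions, and the design decisions taken where more than one reasonable
choice existed. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The point-process model of a single neuron

A spike train is a realisation of a point process on an observation interval
$(t_0, T]$, fully characterised by its conditional intensity
$\lambda(t \mid H_t)$ — the instantaneous spike probability rate given the
spiking history. Discretising into $J$ bins of width $\Delta$ chosen so that
each bin holds at most one spike turns the train into a binary vector
$\Delta N_{1:J}$, and the joint probability of the train becomes a product of
conditionally independent per-bin events.

Two readings of the per-bin mass are implemented in `logLikelihood()`:

* **local-Poisson** (default): $\log p = \sum_k \Delta N_k
  \log(\lambda_k\Delta) - \sum_k \lambda_k\Delta$. This is the discrete form
  whose $\Delta \to 0$ limit is the continuous-time density
  $\sum_j \log\lambda(u_j) - \int\lambda$, which the package also evaluates
  directly (with adaptive quadrature for functional intensities and exactly
  for per-bin step intensities).
* **bernoulli**: $\sum_k [\Delta N_k \log(\lambda_k\Delta) +
  (1-\Delta N_k)\log(1-\lambda_k\Delta)]$, the exact probability of the
  binary vector. It is required wherever probabilities must normalise over
  the binary response alphabet (the information module uses it).

The two agree to second order in $\lambda\Delta$; at the default
$\Delta = 1$ ms and cortical rates ($\lambda\Delta \lesssim 0.05$) the
difference is negligible. All likelihood arithmetic is done in log space
(nats): raw products over $J \approx 10^3$ bins underflow double precision.

Conventions chosen where the mathematics leaves them open:

* bins are half-open, $[t_0 + (k-1)\Delta,\, t_0 + k\Delta)$, 1-based in R;
  a spike exactly at the interval end belongs to the last bin;
* two spikes in one bin are an error by default (`binSpikeTrain` names the
  bin and suggests a smaller $\Delta$); windowed pipeline analyses pass
  `onCollision = "collapse"`, which records one spike with a warning —
  preferable to aborting a 91-window scan because of one coincidence;
* the discrete likelihood and the continuous density differ by the Jacobian
  $n\log\Delta$ of the time-to-bin mapping; `densityScaleLogLik()` removes
  it when the two are compared.

## Intensity estimation by point-process EKF

The conditional intensity is driven by a latent state through an exponential
link, $\lambda_k = \exp(c^\top x_k)$ — guaranteeing positivity — with linear
Gaussian dynamics $x_k = F x_{k-1} + \varepsilon_k$,
$\varepsilon_k \sim N(0, Q)$. The observation at bin $k$ is the spike count
pooled over the $M$ repeated trials of one stimulus; its conditional mean
$M\lambda_k\Delta$ is linearised about the one-step prediction, and the
observation noise variance is set equal to the expected count
$R = M\lambda_k\Delta$ (the Poisson-matching choice, adequate for small
$\Delta$). One `ekfStep()` is the standard predict / innovate / gain /
update recursion; the Joseph-form covariance update is available for
numerical robustness and agrees with the standard form to $10^{-8}$ in the
test suite.

Defaults, units, and rationale:

* $F = I$ (random walk): the least-committal dynamics when nothing is known
  about the temporal structure;
* $Q = 10^{-5} I$ per bin: a slow-drift prior suited to near-stationary
  rates. $Q$ is *the* smoothing knob: it should be of the order of the
  expected squared change of $\log\lambda$ per bin. For the sinusoidal
  log-intensity used in the recovery analyses (amplitude 1, 2 Hz, 1 ms
  bins) that scale is $\sim 10^{-4}$, and the analyses use $10^{-3}$ to
  leave headroom for the filter's causal lag; transient onset responses in
  the worked examples use $5\times10^{-3}$. No EM hyperparameter estimation
  is provided — $Q$ is a user choice, stated with each analysis;
* $x_0 = \log(\max(\bar\lambda, 1\,\mathrm{Hz}))$, $S_0 = 1$: a data-scaled
  neutral start with broad uncertainty;
* $\lambda\Delta$ is clamped to $[10^{-6}, 0.99]$ inside the filter so it
  remains a valid per-bin probability even during large state excursions
  (clamping the top end is announced by a warning).

The returned intensity is the *single-trial* rate
$\hat\lambda_k = \exp(c^\top x_{k|k})$ in Hz; the pooled scale $M$ lives
only inside the filter. The filter is causal (no backward smoothing pass);
fitted intensities therefore lag sharp onsets by an amount controlled by
$Q$, which is visible in goodness-of-fit tests on strongly transient
responses.

## Likelihood projection, classification, separability

`project()` maps an observation to its log-likelihoods under the $P$
stimulus-conditional models. Because the minimum-error Bayes rule depends on
the observation only through these $P$ numbers, the projection loses nothing
for classification while reducing $J$ dimensions to $P$. In likelihood
coordinates the Bayes rule is $\arg\max_i [\ell_i + \log p(s_i)]$ — a linear
discriminant with unit slope — so decision regions are intersections of
half-spaces, hence convex and connected, even when the corresponding
observation-space regions are disconnected. Ties are broken toward the
smallest stimulus index, deterministically. The test suite verifies exact
agreement between `classifyLikelihood(project(x))` and the independent
observation-space route `classifyObservation()` (per-bin masses via
`dpois`/`dbinom`) on every simulated trial.

Cluster separability is quantified by the two-cluster Fisher discriminant
ratio: project on $w = (S_a + S_b)^{-1}(m_a - m_b)$ and return
$(\tilde m_a - \tilde m_b)^2 / (\tilde s_a^2 + \tilde s_b^2)$; with more
than two stimuli the mean over unordered pairs is used (the multi-class
variant is not canonical; the pairwise form keeps each number
interpretable). A singular pooled scatter gets a $10^{-8}$ ridge with a
warning.

One subtlety deserves emphasis, because it determines how the
observation-vs-likelihood comparison must be read. Under per-bin Bernoulli
or local-Poisson models the log-likelihood coordinates are an *affine*
function of the binary vector, and a linear projection can never increase a
Fisher ratio: computed in the raw $J$-dimensional observation space, the
ratio is mathematically at least the likelihood-space one (and its sample
version overfits badly when trial counts are near $J$). What the likelihood
space improves is the low-dimensional geometry the data present: the
comparison `separabilityImprovement()` therefore embeds both spaces into
two dimensions by classical MDS of their max-normalised Euclidean distance
matrices and compares Fisher ratios there, like cluster pictures with like.
On matched-rate, distinct-pattern stimulus pairs the likelihood-space
embedding separates markedly better (the acceptance suite computes the
numbers); `embed = FALSE` gives the raw-coordinate comparison for
completeness.

## Populations as marked point processes

$K$ simultaneously observed neurons are pooled into one event stream whose
events carry the firing neuron's index. Under conditional independence of
neurons given the state — the modelling assumption throughout — the ground
process has intensity $\lambda_G = \sum_c \lambda_c$, marks are multinomial
with $p_c = \lambda_c / \lambda_G$, and the population log-likelihood
$\sum_j [\log\lambda_G(w_j) + \log p_{c_j}(w_j)] - \int\lambda_G$
decomposes exactly into the per-neuron sum — an algebraic identity the test
suite checks to $10^{-10}$ on random instances. Intensities are evaluated
at event times by step-function lookup on the bin grid (no interpolation);
exact spike-time collisions across neurons are ordered by neuron index, with
a warning, so pooling is reproducible. Cross-neuron dependency models are
out of scope.

## Information-theoretic distances

The information a response conveys specifically about stimulus $s_i$ is the
KL divergence between $p(r \mid s_i)$ and the stimulus-averaged
$\bar p(r) = \sum_j p(s_j) p(r \mid s_j)$, in bits (base 2 throughout, for
comparability with the neural-coding literature; the nats/bits conversion
happens only at this module's boundary). Its prior-weighted mean over
stimuli is the mutual information, an identity kept to $10^{-10}$ on exact
tables. In the likelihood space the quantity is estimated by Monte Carlo:
the mean of $\log_2 [p(x \mid s_i)/\bar p(x)]$ over observations recorded
under $s_i$, with the exact Bernoulli likelihood so that $\bar p$ is a
proper mixture mass. The estimator converges to the enumerated value (the
tests enumerate all $2^J$ outcomes for $J \le 10$) with standard error
shrinking as $M^{-1/2}$; no bias correction is applied (none is in scope).

The stimulus distance is $|I_{ssi}(s_i) - I_{ssi}(s_j)|$. The absolute
value (the sign convention is otherwise open) makes the matrix symmetric
with zero diagonal and gives a pseudo-metric: the triangle inequality
holds, but distinct stimuli conveying equal information are at distance
zero — a real limitation of this one-number-per-stimulus geometry.

The sliding-window analyses (`slidingWindowInformation`, `slidingDistance`)
use 100 ms windows stepped by 10 ms by default, refitting the intensity
models inside each window; a $(0, T]$ trial yields
$\lfloor (T - 0.1)/0.01 \rfloor + 1$ windows (91 for $T = 1$ s). The
rate-framework baseline estimates $p(\text{count} \mid s)$ from the
per-window spike-count histogram with Laplace smoothing $\alpha = 0.5$ —
without it a single unobserved count level would send the plug-in KL to
infinity.

## Goodness of fit by time-rescaling

If $\lambda$ is the true intensity, the rescaled intervals
$\tau_j = \int_{u_{j-1}}^{u_j} \lambda\,dt$ (the first integral starting at
$t_0$) are i.i.d. unit exponentials, so $z_j = 1 - e^{-\tau_j}$ are
uniform. `ksTestUniform()` computes the exact sup-distance of the empirical
CDF from the diagonal and compares it with the asymptotic 95% band
$1.36/\sqrt n$; "passing" means the KS plot stays inside the band. The band
constant is the classical KS asymptotic — at $n \approx 40$ it is slightly
conservative relative to the exact finite-$n$ critical value, which is
visible as empirical coverage a shade above 95% in the acceptance
simulation. When only binned data exist, spike times are taken at bin
centres (a documented approximation; no differential rescaling correction
for coarse bins is attempted).

## Stimulus geometry and MDS

Dissimilarity matrices (symmetric, zero diagonal, nonnegative) come either
from Euclidean distances between observation vectors, from $1 - r$
correlation distances between normalised population rate vectors (mean rate
per neuron in a 70–270 ms response window, z-scored per neuron across
stimuli, scaled to unit length), or from the information distance above.
Embedding uses classical Torgerson MDS — double-centre the squared
dissimilarities and keep the two leading eigenvectors scaled by the square
roots of their eigenvalues (delegated to `stats::cmdscale`). Taking
eigenvectors of the raw dissimilarity matrix itself would not be a valid
embedding; the double-centred form is the standard construction. Negative
eigenvalues (non-Euclidean input, e.g. information distances) are truncated
with a warning and the retained fraction of positive dispersion is
reported. Before display, matrices are normalised by their maximum entry —
a convention, stated rather than hidden, since no canonical normalisation
exists.

## The synthetic-data generator

`simulateExperiment()` emulates the structure of a passive-fixation
visual-categorisation study: 36 grey-scale object stimuli in 6 categories,
each repeated ~50 times; 300 ms stimulus, 700 ms interstimulus interval,
100 ms pre-stimulus baseline (trial interval $(0, 1.1]$ s); populations of
up to 100 neurons with category-selective tuning. Those defaults are the
study conditions; analyses that need smaller problems say so explicitly.

Per neuron, the log-intensity is
$\log\lambda(t) = \log b + g_{s}\,\kappa(t - t_{on} - \ell)$ with baseline
$b \approx 5$ Hz (log-normal across neurons), a transient-plus-decay kernel
$\kappa(u) = (u/\tau)e^{1-u/\tau}$ ($\tau = 60$ ms, peak 1), latency
$\ell \sim N(80, 10)$ ms, and gains $g$ drawn around 1.8 for the neuron's
preferred category (peak rate $\approx b\,e^{1.8} \approx 30$ Hz) and 0.4
elsewhere, plus per-stimulus jitter (SD 0.15) so stimuli within a category
remain distinguishable. These values are ordinary for inferior-temporal
cortex-like selectivity: spontaneous rates of a few Hz, evoked transients a
few tens of Hz, ~100 ms latencies.

Spike times are drawn by Lewis–Shedler thinning — candidates from a
homogeneous process at a majorant rate, kept with probability
$\lambda(t)/\lambda_{max}$ — which is exact in continuous time for bounded
intensities; per-bin Bernoulli draws exist in the test helpers where speed
matters and exactness does not. Marked population recordings can be drawn
either neuron-by-neuron or generatively from the ground process with
multinomial marks; the two are distributionally equivalent and the tests
compare their count and mark statistics.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: no refractoriness or burstiness (the processes
are inhomogeneous Poisson, so within-trial history effects are absent), no
trial-to-trial gain drift or adaptation across repetitions, no correlated
variability between neurons, no eye-movement or attentional covariates.
Results on synthetic data certify the estimators and the algebra, not the
biology.

## Problem sizes and determinism

The test suite runs everything on deliberately small problems: tens of
trials, $J \le 10$ for exact enumerations, 200 realisations for coverage,
$4\times10^4$ Monte-Carlo samples for the information oracle — sizes at
which every check completes in seconds while leaving the statistical
margins meaningful. Every stochastic test and the acceptance script seed
the RNG explicitly; `simulateExperiment` requires a seed and reproduces its
dataset bit-for-bit.

## Known limitations

* The filter is causal; without a smoothing pass, estimates lag sharp rate
  onsets (choose $Q$ accordingly).
* The exponential link takes a linear-in-state log-intensity; nonlinear
  state equations and biophysical (integrate-and-fire) generators are out
  of scope.
* The information distance compresses each stimulus to one number before
  differencing; stimuli with equal specific information collapse.
* Plug-in information estimates carry small-sample bias; no correction is
  applied.
* Continuous-time exact filtering and spike-sorting/waveform handling are
  out of scope; binned data are assumed faithful at the chosen $\Delta$.
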