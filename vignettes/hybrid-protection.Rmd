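---
title: "Hybrid protection of gait biometrics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid protection of gait biometrics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitshield)
```

## The problem

Gait is a biometric: a sequence of 2D body keypoints extracted from a
walking video identifies its owner, and in a screening context it also
carries a diagnostic label. A hospital that sends gait features to a
server for processing therefore leaks sensitive data twice over — the
features themselves are re-identifiable, and unlike a password a gait
cannot be revoked. `gaitshield` implements a hybrid protection scheme
for this setting: the additively homomorphic Paillier cryptosystem
protects the features in transit and during server-side computation,
and a cancelable-biometric Gaussian random projection — executed
*inside* the ciphertext domain — turns them into revocable,
noninvertible templates before any classifier sees them. The classifier
itself (an LSTM with multiplicative attention) runs on transformed data
only, so it needs no cryptographic modification at all; the protection
is independent of the network architecture.

The threat model is the usual "honest-but-curious server": the
projection server follows the protocol but would read any plaintext it
is given. Under the scheme it only ever handles ciphertexts; the
private key and the plaintext features stay with the client, and the
machine-learning server receives only projected templates from which
the original features cannot be reconstructed (see the noninvertibility
argument below).

## The Paillier layer

Keys are built from two random primes $p \ne q$ of equal bit length:
$n = pq$, $g = n + 1$, and

$$\lambda = (p-1)(q-1), \qquad \mu = \lambda^{-1} \bmod n .$$

Encryption of an integer $f$ with a fresh randomizer $r$ coprime to $n$
is $c = g^f r^n \bmod n^2$, and decryption is
$f = L(c^{\lambda} \bmod n^2)\,\mu \bmod n$ with $L(x) = (x-1)/n$.
Because $g = n+1$, the binomial identity gives
$g^f \equiv 1 + fn \pmod{n^2}$, which both speeds up encryption and
makes the decryption identity elementary. Note that this $\lambda$ is
the *product* form $(p-1)(q-1)$ with $\mu$ its inverse modulo $n$; the
classical presentation uses $\mathrm{lcm}(p-1, q-1)$ instead. Both are
valid decryption keys for $g = n+1$, but keys produced by this package
are not interchangeable with third-party Paillier implementations that
serialize the lcm form — a deliberate choice, recorded here for
interoperability awareness.

Two properties carry the whole scheme:

* products of ciphertexts decrypt to sums of plaintexts, and
* a ciphertext raised to an integer power decrypts to the plaintext
  scaled by that integer.

Real-valued gait features enter this integer world through a signed
fixed-point encoding: value $x$ at decimal scale $s$ becomes the
mantissa $\mathrm{round}(x \cdot 10^{s}) \bmod n$, and residues above
$n/2$ decode as negative (half-range convention). The default scale is
$10^{-6}$ for both features and matrix entries. With 64-bit primes
(a 128-bit modulus, the configuration used throughout), the worst-case
accumulated inner-product magnitude
$j \cdot \max|x| 10^{6} \cdot \max|m| 10^{6}$ stays some twenty decimal
orders below $n/2$, and `overflow_bound_ok()` verifies the bound in
exact big-integer arithmetic before any encrypted run; the guard is
deliberately strict (it rejects even a product equal to $(n-1)/2$).

Big-integer arithmetic is provided by OpenSSL's BIGNUM through a small
Rcpp layer; primality uses OpenSSL's Miller–Rabin-based
`BN_check_prime`. Prime candidates have their top bit forced and
keypairs are regenerated until the modulus has exactly twice the prime
bit length, so "128-bit keys" is a guarantee, not an expectation. Two
entropy channels exist: OS cryptographic entropy for production keys
and randomizers, and R's seedable RNG for reproducible test keys —
seeding is an explicit opt-in (`crypto_seed`, `seeded_r`), never the
default.

## The cancelable projection

A seeded matrix $M \in \mathbb{R}^{j \times q}$, $q < j$, with i.i.d.
$N(0, 1/q)$ entries maps a feature vector $x$ to the template
$y = xM$. Three facts make this a biometric protection:

* **Noninvertibility.** Recovering $x$ from $(M, y)$ means solving
  $M^{\mathsf T} x = y$: $q$ equations in $j > q$ unknowns. A Gaussian
  matrix has full column rank $q$ almost surely, so the system is
  consistent but underdetermined and has an affine space of solutions
  of dimension $j - q$. `rp_verify_noninvertibility()` makes this
  constructive: it reports the rank and returns two distinct preimages
  (a minimum-norm solution and its translate by a null-space vector of
  $M^{\mathsf T}$) that both reproduce $y$ to $10^{-9}$.
* **Renewability.** The matrix is a deterministic function of a seed
  (a pinned Mersenne–Twister generator with inversion sampling, so
  seeds reproduce across platforms). Rotating the seed revokes a
  compromised template and issues a new one from the same gait;
  `rp_renew()` refuses a no-op renewal with an unchanged seed.
* **Key-independence.** The projection commutes with encryption:
  decrypting the encrypted-domain projection yields, at integer level,
  exactly the plaintext product of quantized mantissas, whichever
  keypair carried it. Two hospitals with different keys therefore
  obtain bit-identical templates from the same features and matrix,
  and can compare templates without sharing keys.

In the ciphertext domain the product $y = xM$ becomes, per output
component, $\prod_i c_i^{\,m_{ik}} \bmod n^2$ — ciphertext
exponentiation by the quantized matrix mantissas followed by ciphertext
multiplication, which is the only way a linear map can be evaluated
under an additively homomorphic scheme. Matrix entries are quantized to
integers ($\mathrm{round}(m \cdot 10^{6})$) because modular
exponentiation needs integer exponents; the resulting template differs
from the real-valued projection by at most the quantization error,
while the integer-level result is exact and is what the tests assert.

The default transformed length is $q = j - 1$. Protection of a
recording is applied per frame with the same matrix across frames and
subjects (the matrix, not the data, is the shared secret); the pooled
30-slot summary vector can be protected the same way when a single
vector per recording is preferred.

## Feature extraction

The pipeline from raw multi-person keypoint frames to features is:
subject isolation (nearest-neighbour assignment in summed Euclidean
distance to the previous frame's selection), per-keypoint
constant-velocity Kalman filtering, then spike removal and linear
interpolation of missing samples.

The Kalman defaults deserve a note, because they were a genuinely open
design point. With image-scale walking data the limbs oscillate at
roughly stride frequency with tens of pixels of amplitude, so peak
accelerations are of order $2000\ \mathrm{px/s^2}$. A
constant-velocity filter only tracks that if its process noise admits
it: the default `process_var = 4e6` (the square of that acceleration)
and `meas_var = 4` ($2\,\mathrm{px}$ estimator jitter) keep the filter
honest about fast limbs while still attenuating noise. A much smaller
process variance — an otherwise natural-looking default — makes the
filter lag the ankles by ~10 px and *adds* error instead of removing
it. The filter also applies a 6-standard-deviation innovation gate so
an isolated coordinate spike is rejected rather than absorbed;
whatever survives is caught afterwards by the spike rule (step
displacement above `spike_factor = 5` times the median step) and
refilled by linear interpolation between the nearest valid neighbours.
Detections with confidence below 0.1 are treated as missing from the
start.

From the cleaned track, per-step channels follow the stepwise
definitions ($\Delta x_i$, $\Delta y_i$, $d_i$, $v_i = d_i/\Delta t$,
component velocities, and acceleration). Two conventions are worth
flagging:

* **Acceleration** defaults to the ratio form $a_i = v_i / \Delta t$,
  with the conventional finite difference
  $a_i = \Delta v_i / \Delta t$ available via
  `acceleration = "difference"`. The ratio form is dimensionally a
  shortcut (it rescales speed rather than differentiating it), but it
  is kept as the default deliberately; the switch exists for users who
  want the physical quantity.
* **Tangent angle** uses the two-argument arctangent
  $\rho_i = \mathrm{atan2}(\Delta y_i, \Delta x_i)$ rather than
  $\tan^{-1}(\Delta y/\Delta x)$. Subjects walk the track in both
  directions, and the one-argument form aliases a direction reversal
  onto the same angle; the quadrant-aware form keeps the two walking
  directions distinguishable.

The five corner angles (nose–neck–hip, neck–hip–knee,
shoulder–elbow–wrist, hip–knee–ankle, right knee–hip–left knee) are
interior angles at the middle joint in $[0, \pi]$. The single-sided
ones are computed on a selectable side (right by default, since the
five-angle set does not specify a side); nose–neck–hip and
knee–hip–knee use the hip midpoint.

The sigma-lognormal decomposition models the speed profile as a sum of
lognormal strokes
$v(t) = \tfrac{D}{\sigma\sqrt{2\pi}(t-t_0)} \exp\!\big(-\tfrac{(\ln(t-t_0)-\mu)^2}{2\sigma^2}\big)$
and extracts them greedily: largest residual mode, bounded
Levenberg–Marquardt fit seeded from the mode's location and width,
subtract, repeat until the residual energy drops below 5% of the input
or eight strokes have been taken. On noiseless synthetic strokes the
fit recovers $D$, $\mu$, $\sigma$ essentially exactly; on real speed
profiles the decomposition is a descriptive summary, not an inverse
problem with a unique answer.

The pooled length-30 feature vector is: mean of each of the 10
temporal channels, standard deviation of each, mean of each of the 5
corner angles, and 5 sigma-lognormal globals (stroke count; means of
$D$, $\mu$, $\sigma$, $\theta$). This layout is this package's own
documented convention — a 30-slot composition is required but not
universally standardized, and ours makes no claim of matching any
particular prior system's slots.

## The classifier and the ablation

The network is: LSTM (32 units) → dropout (0.3) on the hidden-state
sequence → multiplicative attention with trained bilinear score
$\mathrm{score}(h_t, h_s) = h_t^{\mathsf T} W h_s$ → dense (10 units,
ReLU, L1 penalty 0.002) → 2-way softmax, trained with RMSProp on
binary cross-entropy. The attention wiring is Luong-style: the query is
the hidden state at the last valid step, scores over all steps are
softmax-normalized into weights, and the weighted sum of hidden states
(the context vector) feeds the dense stack. Only the score function is
externally fixed; the surrounding wiring (query choice, normalization,
readout) is this package's documented decision. The implementation is
plain R — forward pass and backpropagation through time — which keeps
training exactly reproducible under a seed; the gradients are verified
against numerical differentiation in the test suite. Training defaults
(100 epochs, batch 16, learning rate $10^{-3}$, no early stopping) are
package choices; early stopping is off so that the two ablation arms
see identical optimization schedules. Dropout masks are redrawn per
batch and applied to the readout path only, not the recurrence;
inference disables dropout entirely.

Evaluation is interpatient: no subject contributes recordings to both
the training and test side of a fold. Each fold draws a class-balanced
training set (14 + 14 subjects when each class has at least 15;
otherwise a proportional ~70% per class, which a 10 + 10 synthetic
cohort uses as 7 + 7) and tests on everyone else. The ablation runs the
identical fold plan twice — same assignments, same initialization and
training seeds, verified by a digest of the fold structure — with the
protection pipeline (encrypt → project in ciphertext → decrypt)
inserted between features and classifier in the protected arm only,
using a fresh projection matrix per fold. The difference table
$\Delta = \text{protected} - \text{unprotected}$ per metric is the
scheme's performance cost.

## What the synthetic cohort does and does not show

The generator emulates the *structure* of a two-class hospital gait
study: sagittal view, 2–3 recordings per subject in both walking
directions, missing keypoints and coordinate spikes, and a
dementia-like class with reduced speed (0.65 vs 1.2 m/s), raised
stride-time variability (CV 0.10 vs 0.03) and reduced arm swing (0.15
vs 0.45 rad). Subjects vary around their class profile by ~8%
(log-normal) on speed and cadence. These magnitudes are documented
defaults chosen to give the classifier a learnable but noisy signal;
they are not claims about real dementia effect sizes. Consequently the
ablation on synthetic cohorts demonstrates that the *protection scheme*
preserves performance (the paired $\Delta$), and that the pipeline is
correct end to end — it does not demonstrate clinical accuracy, and
absolute accuracies on synthetic walkers (which are easier to separate
than real patients) should not be read as such. Kinematically the
walker is a stick model with sinusoidal joint drives; it has no ground
contact, double-support phase, or soft-tissue artifacts.

Problem sizes used by the shipped tests were chosen to exercise the
study configuration where it matters (128-bit keys, $j = 30$,
$q = 29$ for the projection checks; 100-keypair key-size law) and a
scaled-down cohort where training time dominates (20 subjects, 3
recordings each, 5 folds, 120-frame recordings); the full encrypted
route is used in the scaled ablation, about 0.8 s per recording per
fold at these sizes.

## Numerical and degenerate-input choices

* Quantized mantissas and exponents live in exact big-integer
  arithmetic end to end; equality claims in the tests are
  string-identical integer comparisons, not floating-point closeness.
* The overflow guard is strict at the boundary and refuses the run
  before any ciphertext is produced.
* Rank decisions in the noninvertibility verifier use the SVD with the
  standard `max(dim) * eps * largest-singular-value` cutoff; an
  inconsistent target (a `y` no preimage can produce) is reported with
  a flag and no witnesses rather than an error.
* An all-zero speed profile yields zero strokes (not an error); a
  keypoint channel with no valid sample at all is an explicit
  `unrecoverable-channel` error.
* Sequences shorter than two frames cannot produce kinematics and are
  rejected; leading/trailing missing samples take the nearest valid
  value rather than being extrapolated.

## Known limitations

* The product-form $\lambda$ makes keys non-portable to lcm-based
  Paillier implementations (templates, being plaintext after
  decryption, are unaffected).
* Paillier ciphertexts expand each 6-decimal-digit feature to 256 bits;
  the scheme is practical for feature vectors, not raw video.
* The projection's noninvertibility argument is information-theoretic
  about a *single* template; an adversary holding many templates of the
  same subject under the same matrix learns more than one equation
  system. Seed rotation (renewability) is the mitigation.
* The LSTM is intentionally small and CPU-bound; it is the reference
  architecture for the ablation, not a tuned diagnostic model.
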