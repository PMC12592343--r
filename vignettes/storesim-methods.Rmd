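---
title: "Interaction-aware generative crowd simulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-aware generative crowd simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`storesim` learns and simulates socially responsive pedestrian trajectories in
indoor retail spaces. This vignette is the package's account of the science:
the representation, the model, the simulation loop, the evaluation suite, the
synthetic ground-truth generator used in place of proprietary positioning
data, and the numerical and design choices behind each.

## The representation: space as language

A store floor is discretised into a square grid of `2^depth` cells per side
(`grid_spec()`). Every cell is named by a fixed-length string in which the
character at position *d* records the quadrant chosen at recursion level *d*
of the subdivision, drawn from that level's private 4-letter block (level 1:
a–d, level 2: e–h, ...). Two properties make this encoding suitable as a
"spatial vocabulary":

* **locality** — cells sharing a length-*p* prefix lie in the same
  `2^(depth-p)`-cell square (`prefix_region()`), so sub-word structure carries
  geometric meaning a sequence model can exploit;
* **level identifiability** — the blocks are disjoint, so the subdivision
  level of any character is recoverable from the character alone, which makes
  malformed tokens detectable locally (`validate_code()`).

The quadrant index within a level is `2*row_bit + col_bit` (Z-order) with the
origin at the lower-left corner. Published examples of such codes constrain
the block structure but not the within-level letter ordering; the Z-order
convention is pinned here and used consistently, which every internal
property (round-trips, locality, validation) depends on — none depends on the
specific choice.

Cell indices are 0-based and physical cells are half-open intervals
`[k*s, (k+1)*s)`, so a point on a boundary belongs to exactly one cell.
Non-square and non-power-of-two grids are rejected at construction: the
fixed-length code and the alphabet budget both assume the dyadic square.

## Multi-agent documents and asymmetric loss masking

Trajectories sampled every 5 s (`trajectory_table()`) are serialised into
whitespace-separated symbolic documents (`build_document()`). Each timestep
of a focal customer contributes `1 + k` words: `S<code>` for the focal
position, then the positions of the `k` nearest neighbours in rank order
(`O…`, `T…`, and `U…` for `k = 3`). `k = 2` is the reference configuration;
`k = 0` is the non-interactive control, produced by the same code path.
Neighbour rank is by Euclidean distance between cell centers, with distance
ties broken by ascending agent id — an arbitrary but deterministic rule.

Design choices worth recording:

* **Absent neighbours.** Stores are often nearly empty, so neighbour slots
  frequently have no occupant. A dedicated placeholder word (`Onone`,
  `Tnone`) keeps frame arity constant, which simplifies both masking and
  constrained generation. The placeholders are seeded as atomic symbols in
  the sub-token codec.
* **End of trajectory.** A reserved single word (`Z` by default) terminates
  every training document. Since leaving the store is a focal decision the
  model must learn to emit, the end word appears in training documents and is
  a masked-in prediction target, not only a generation stop.
* **Asymmetric loss masking.** Only sub-tokens belonging to focal (`S`) words
  — plus the end word — are prediction targets (`encode_with_mask()`).
  Neighbour words condition the model but contribute exactly zero to the
  loss and its gradient (`masked_loss()`, `masked_loss_grad()`): agents
  observe others but only their own behaviour is learned. The mask lives at
  the loss level; attention is unrestricted.

## Sub-token codec

A byte-pair-encoding codec (`train_codec()`) is trained from scratch on the
document corpus with a deliberately small vocabulary (200 for the full-store
64 × 64 configuration). The intent is that each role word decomposes into a
few reusable sub-tokens — shared quadrant prefixes become shared sub-tokens —
so the model generalises across nearby locations instead of memorising whole
cells. Implementation properties:

* merges never cross whitespace, and training is deterministic (pair-count
  ties break lexicographically), so a corpus and budget fully determine the
  codec;
* the base alphabet is seeded from the grid (every quadrant letter the grid
  can produce plus the role prefixes), so all well-formed words are encodable
  even if some cells were never visited in training;
* decoding is exact: sub-tokens concatenate back into words, and word
  boundaries are recovered from the closed grammar (every word starts with an
  uppercase role prefix);
* `decomposition_report()` audits the sub-tokens-per-word distribution
  against the 2–4 design band and flags violations rather than silently
  accepting them. The band is a property of the full-scale configuration
  (4096 cells force decomposition under a 200-entry budget); on the small
  desk world the same budget covers most words whole, and the report says so.

## The sequence model

The generator is a GPT-2-style decoder-only transformer implemented in
matrix-level R with hand-written backpropagation (no deep-learning runtime is
used): learned token and positional embeddings, pre-layer-norm blocks of
causal multi-head self-attention and a GELU MLP (expansion 4), a final layer
norm, and an output head tied to the token embedding. Two presets exist
(`model_config()`):

| preset | layers | heads | hidden | context | use |
|--------|--------|-------|--------|---------|-----|
| `full` | 12     | 12    | 768    | 6144    | full-scale reference configuration |
| `desk` | 2      | 4     | 128    | 768     | CPU-scale training and testing |

Training (`train_model()`) uses AdamW (decoupled weight decay 0.01, applied
to weight matrices only), the reference recipe's learning rate 3e-4 and batch
size 32 as defaults, a linear warmup–decay schedule (10% warmup, decay to 10%
of peak — the specific schedule shape is a package choice), gradient
accumulation over documents, early stopping on validation loss, and a
90/10 train/validation split **by document** so no trajectory leaks across
the split. Documents longer than the context window are truncated from the
head in whole-frame units, keeping the most recent context. The correctness
of the backward pass is pinned by finite-difference tests, and the masking
contract — exactly zero gradient at masked-out positions — is asserted
exactly, not approximately.

For the desk-scale experiments the package uses a higher learning rate
(1e-3) and small batches (6): with corpora of one-to-two hundred short
documents, the reference recipe's 32-document batches would yield too few
optimiser updates to converge. These values were chosen on validation loss.

## Constrained generation

At simulation time the model must emit exactly one well-formed focal word (or
the end word) per step. Instead of sampling freely and rejecting malformed
output, sampling is constrained by a prefix trie over the sub-token id
sequences of every admissible word (`focal_token_trie()`,
`next_focal_token()`): at each sub-token step only continuations that can
still complete to `S<code>` for some grid cell, or to the end word, are
allowed. Because codes are fixed-length and decoding is injective, no word's
id sequence is a strict prefix of another's, so completion detection is
unambiguous. Malformed output is impossible by construction, which is also
asserted downstream (every simulated cell validates against the grid).
Rejection-style sampling was considered and discarded: it is slower, needs an
arbitrary retry cap, and its failure mode (a silent fallback) is harder to
test. Sampling supports temperature and top-k; simulations default to
temperature 1 (the model's learned distribution, unsharpened).

Generation uses per-sequence key/value caches (`decode_state()`,
`decode_append()`), so appending a frame costs one incremental forward pass
rather than a full-context recomputation; cached and full forward passes are
tested to agree to numerical precision.

## The simulation loop

`run_simulation()` grows a whole crowd from one trained model:

1. **Arrivals.** A fixed-interval schedule (exactly `rate × duration`
   entries, the first at half an interval) is the default because it realises
   the nominal arrival rate exactly; a seeded Poisson process is available
   (`arrival_mode = "poisson"`). The eight benchmark rates span 0.15–12
   persons/min (9–720 per hour).
2. **Seeding.** Each arrival replays the first three positions of a donor
   trajectory drawn uniformly from a seed pool (here: a held-out split of the
   synthetic ground truth; donors shorter than three ticks are excluded).
3. **Synchronous generation.** Per 5-s tick, every post-seed agent samples
   its next position from its own stored context; all moves are staged and
   applied simultaneously, so no agent's new position can influence another
   agent's decision within the same tick. Each agent then appends the
   realised frame — its new position plus its neighbours' new positions in
   rank order — to its context. Past frames are stored, not recomputed: an
   agent's history is exactly what it "saw" at each past tick.
4. **Departure.** An agent leaves when it samples the end word or reaches
   `max_steps` (default: the longest stay the context window can condition
   on); the run ends when arrivals are exhausted and the store has drained.

Every stochastic choice derives from the run seed through per-agent RNG
substreams (snapshot/restore of the R RNG state), which makes runs bitwise
reproducible and — more importantly — independent of the order agents are
iterated within a tick. Conservation (arrivals − departures = active count at
every tick) is asserted from the output table alone.

`replay_generate()` implements the controlled-ablation mode: a single
model-driven focal agent moves through a recorded background crowd, so
interaction-aware and non-interactive models can be compared under identical
densities without compounding model errors.

**Warm-up exclusion.** Analyses use the equilibrium phase only.
`equilibrium_window()` takes the smallest tick from which the 10-minute
rolling mean of the active count stays within ±10% of the remaining-run mean,
with two guards: the window must span at least half the run (otherwise the
drain-out tail after arrivals stop would qualify trivially), and a series
that never stabilises falls back to a flagged fixed warm-up. Sparse runs
(long stretches of 0–1 occupancy) rarely "stabilise" under a relative band,
so the fallback is the common path at the lowest rates.

## Evaluation metrics

`evaluate_tables()` compares two trajectory tables with six behavioural
metrics: cell occupancy maps; per-agent stay, travel distance and mean speed;
big-turn ratio (≥ 90°) by distance-to-nearest-agent bin; mean speed by
(nearest, second-nearest) distance pair; mean speed by local density (agents
in the 3 × 3 block centered on the focal cell, focal included, so the minimum
is 1; densities above 5 pooled); and the RMSE between ordinary-least-squares
quadratic fits of stay duration (or travel distance) against crowding,
evaluated on the shared crowding levels.

Operational definitions the source material leaves open, fixed here:

* per-tick speed is the outgoing displacement over 5 s, with stationary ticks
  counted as speed 0; proximity bins use distances at the step's starting
  tick (the decision context);
* turning angles adjacent to a stationary step are skipped, not imputed, and
  an empty bin reports `NA`, never 0;
* the crowding level experienced by an agent is the mean number of
  concurrently present agents over its visit, rounded to an integer class;
  the dwell-time comparison splits classes at 6;
* distance bins default to 0.5 m steps from 0 to 5 m.

All metrics are pure functions of their inputs; purity, closed forms
(straight walkers, offset quadratics), and brute-force oracles (per-step
distance sums, exhaustive 3 × 3 counts, normal equations) are tested.

## The synthetic world

The positioning data the reference system was trained on is proprietary, so
the package ships a rule-based generator (`generate_world()`) that emulates
its structure: 5-s sampling, entry and exit at the store edge, goal-directed
movement, and three planted, labelled interaction effects —

* **slowdown**: a neighbour within `r_slow_m` (default 1 m) multiplies the
  per-tick move probability by `slow_factor` (default 0.5);
* **reroute**: a neighbour within `r_turn_m` (default 1 m) replaces the
  goal-directed step with an orthogonal detour with probability `p_turn`
  (default 0.3);
* **early disengagement**: local 3 × 3 density at or above
  `disengage_density` (default 3) drops all remaining goals with per-tick
  probability `p_disengage` (default 0.05).

Every tick carries exactly one label (`free`/`slowed`/`rerouted`/
`disengaged`, in that order of precedence: a skipped move is `slowed`, a
detour `rerouted`, a goal drop `disengaged`), giving downstream tests planted
signals with known ground truth. The default desk world is a 16 × 16 grid of
0.5-m cells — one step per tick is 0.1 m/s, slower than free walking but in
the stop-and-browse range typical of shoppers; what matters for the method
is the *relative* modulation of speed, turning and dwell, not absolute pace.
The generator is deliberately a simple cellular rule system, mechanically
unrelated to the transformer it feeds, so model-vs-truth agreement is a
genuine recovery test rather than self-confirmation.

What the synthetic world does **not** emulate: store layout and shelf
geometry (no obstacles), heterogeneous customer types, group shopping,
sensor noise and dropouts, and basket-carrier sampling bias. Passing
recovery tests on this world therefore demonstrates that the pipeline can
learn and reproduce planted social responses at CPU scale — not that it
matches any particular real store.

A note on the interplay of the planted rules: slowdown *lengthens* crowded
visits while disengagement *shortens* them, so the net stay–crowding curve
is a balance. The generator's tests therefore check the disengagement signal
directly (more goal-drop events and shorter disengaged visits under
crowding) rather than asserting a net direction.

## End-to-end recovery experiment

`recovery_experiment()` is the scaled-down analogue of the full validation
study, sized for a single CPU: ground-truth worlds at arrival rates 0.3,
1.2 and 2.4 persons/min (40 agents each by default); `k = 2` and `k = 0`
corpora from the same trajectories; a 200-entry codec; the desk model
trained with early stopping (the experiment suite caps it at 25 epochs;
typical stops are at 10–20); simulation at 0.3 and 2.4 persons/min (about 30
and 60 arrivals); equilibrium filtering; then three sign-level checks —
congestion slows simulated agents (density ≥ 3 vs 1), big turns concentrate
near other agents (< 1 m vs ≥ 2 m), and the interaction-aware model tracks
the ground-truth crowding–stay quadratic better than the non-interactive
one. One run takes roughly 3–5 minutes; these problem sizes balance
recoverability of the planted effects against single-CPU runtime, and they
are the sizes the test suite and the acceptance script use (the stochastic
end-to-end check is run across three seeds with a majority rule).

## Known limitations

* The desk model is orders of magnitude smaller than the full-scale
  configuration, and desk corpora are thousands, not millions, of
  transitions; simulated motion is noisier than the rule-based ground truth
  (higher turn ratios overall, residual multi-cell steps), and sign-level
  recovery — not magnitude matching — is the appropriate bar at this scale.
* Not every planted effect is recoverable at desk scale. The slowdown
  conditional (stay in place when someone is near) and the crowding–stay
  curve are; the proximity-linked *turning* contrast is not: the desk model
  does not learn directional persistence (teacher-forced next-cell accuracy
  stays near chance among adjacent cells), so its big-turn ratio sits at a
  noise floor of 0.6–0.8 in every distance bin and the near-vs-far contrast
  drowns. The corresponding end-to-end test documents this as a failing
  assertion rather than weakening the check; temperature changes and a 1.5×
  data increase were tried and do not flip the sign.
* BPE's 2–4 sub-token band is a bulk property of the full-scale corpus; a
  small tail of rare words decomposes longer and is flagged by
  `decomposition_report()`.
* The simulator allows co-located agents (no collision constraint), matching
  the representation's assumptions; physical exclusion would need a
  different decoding constraint.
* Training is single-threaded matrix R: adequate for the desk preset,
  impractical for the `full` preset, which is provided as a configuration
  reference, not a trained artifact.
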