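---
title: "Cultural-mindset decision models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cultural-mindset decision models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindsetmdp)
```

## The task and the two players

The simulated task drops a newcomer into a village with an unfamiliar
formality norm: old and young villagers prefer formal address, the
middle-aged prefer informal. The player must learn this norm from
villager reactions while pursuing a concrete quest — finding out where
the water source is. Play is a sequence of discrete choices: select a
villager age class to approach, greet formally or informally, ask for the
water formally or informally (the request is resolved once per
conversation: the villager either gives directions on the first ask or
does not), leave the conversation, or stop playing.

Two cognitive profiles play this task. The **fixed** mindset arrives with
strong preset beliefs — certain that old people like formality, certain
that young people do not, suspecting the middle-aged do — values task
completion far above cultural certainty, pays a high cost per move, and
does not expect its beliefs to change unless it is completely uncertain.
The **malleable** mindset arrives agnostic, values full cultural
understanding above even the quest reward, pays a lower cost per move,
and expects to learn whenever a belief is not yet at an extreme.

## Model structure

Each profile is a discrete MDP over the belief-augmented state space of
nine integer variables: the three formality beliefs (−2..2 each),
`in_conv`, `npc_age`, `greeted`, `asked`, `npc_happy`, and `got_water` —
16,000 states in all. Beliefs are state variables, so partial
observability of the culture is handled by folding discretized beliefs
into a fully observable state.

Two transition models share this space:

* the **subjective model** (what the player expects) drives planning. A
  greet or ask is expected to please the villager with probability equal
  to the player's own belief that the class likes the formality used,
  linearly mapped as $(b+2)/4$; an unresolved ask is expected to reveal
  the water with the environment's reveal probabilities (both mindsets
  share this basic task reasoning); and the player's anticipated belief
  change follows its mindset: at $b = 0$ a one-step move in whichever
  direction the (unpredictable) feedback indicates; at $|b| = 1$ the
  malleable player expects confirming feedback to strengthen the belief
  and does not anticipate unlearning, while the fixed player expects no
  change at all; $|b| = 2$ is a fixed point for both. Anticipated changes
  occur at the player's own updating propensity (0.95 / 0.6 for
  malleable at $|b|$ = 0 / 1; 0.6 for fixed at 0), i.e. the player knows
  roughly how much evidence it needs.
* the **real-world model** generates outcomes. Reactions follow the true
  norm exactly; after any feedback the concerned belief moves one step
  toward its correct value with a probability keyed on the current value
  (fixed: 0.20/0.40/0.60/0.80 from −2 to +1 — confirmation bias;
  malleable: 0.30/0.60/0.95/0.60 — peaked at uncertainty; 0 at the
  correct extreme; the table mirrors for a class whose correct value is
  −2). Belief trajectories are therefore monotone toward the truth, at
  most one step per feedback event.

Rewards are granted at the end of play — +5 for the water plus a single
belief-strength band reward (0.5/1.5/3.5 fixed, 1/3/6 malleable for
strengths 1–2, 3–5, 6) — except the constant per-move time cost (−0.75
fixed, −0.5 malleable), which accrues on every action including
navigation and stopping.

## Solving and simulating

`q_iteration()` iterates the softmax-consistent Q fixed point with
sparse-matrix backups over the full space; with `beta = Inf` (the
pipeline default) the inner policy expectation is the greedy maximum and
the procedure is standard value iteration. Terminal value is zero and the
end-of-play reward is attached to the STOP transition. Convergence is
declared at a sup-norm residual below `tol = 1e-6` (both water-task
models converge in ~20–40 sweeps, under two seconds each).

Each profile's Q table is solved **once** per environment and shared by
all simulated players of that mindset: the noise parameter β is a
decision-time quantity (Boltzmann sampling over the actions available in
the current state), not a planning-time one. A cohort draws one
β ~ lognormal(0, 1) per player pair — median 1, so half the cohort plays
quite noisily — and simulates one fixed and one malleable player per
draw, with per-record seeds derived deterministically from the master
seed so any record is re-simulable in isolation.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.98 | discount in the Q recursion |
| `tol`, `max_iter` | 1e-6, 10000 | solver convergence control |
| `solve_beta` | `Inf` | inner-policy β at solve time |
| `p_reveal_happy` / `p_reveal_unhappy` | 0.8 / 0.1 | water-reveal probability on a conversation's first ask |
| `max_steps` | 50 | episode cap (`end_reason = "cap"`) |
| `n_players_per_mindset` × `runs_per_player` | 50 × 20 | scaled study conditions (full 500 × 100 design via `full_scale = TRUE`) |
| classification grid | log β ∈ [−2.5, 2.5] step 0.125 | profile-likelihood grid |

**Why γ = 0.98.** All substantive rewards arrive at episode end, and the
per-move time cost already implements time preference; heavy additional
discounting would double-count it and erase the terminal goals that
define the mindsets (at γ = 0.9 a ten-move plan retains only ~35% of its
terminal reward and the solved malleable policy simply stops without
learning). γ = 0.98 keeps terminal rewards salient over typical 10–15
move episodes (0.98¹⁰ ≈ 0.82) and sets the effective horizon 1/(1−γ) =
50, matching the episode cap, while retaining a strict contraction.

**Why confirmation-shaped subjective updating.** A fully symmetric
"belief moves toward whatever the feedback says" expectation makes the
$|b| = 1 \to 2$ step a martingale (expected certainty gain +0.5 versus
+1 for greeting a fresh class at 0), so the planned-optimal malleable
strategy degenerates into one-turn belief-sampling conversations — the
opposite of an explore-and-learn player. Expecting evidence to *confirm
and strengthen* a formed lean (and not anticipating unlearning) restores
coherent within-conversation learning while keeping the 50/50
split under complete uncertainty. The kernel is a plain function in the
profile object and can be swapped.

**Why the request resolves once per conversation.** If every repeated
ask could reveal the water, re-asking with the wrong formality forever
(0.1 per ask) would dominate fixed-mindset play and the `asked` state
flag would carry no meaning. Resolving the request on the first ask of a
conversation matches the task's narrative logic — the villager either
gives directions or does not, and the player moves on — and gives
`asked` its semantics. Dialog (and hence cultural learning) remains
available after the water is known; a resolved request simply cannot be
re-rolled.

## Behavioral criteria and statistics

Per play record the package computes: the **learning score**
$\sum_X |LF(X)_F - LF(X)_0|$ (maximum 7 from the fixed initials, 6 from
the malleable); **conversations** (one per villager selection) and
**dialog turns** (greet/ask actions only — navigation is not dialog);
**conversational quitting** (a water-seeking conversation left without
gaining the water information in fewer than 4 dialog turns; conversations
opened after the water is known cannot gain it and are outside the
quitting universe) and **game quitting** (ending without the water after
fewer than 3 conversations); and **responsiveness** (an
incorrect-formality use followed later in the same conversation by at
least two correct uses, judged against the true culture; conversations
with no incorrect use are not applicable — the two later uses need not be
consecutive).

Score comparisons aggregate per player first and use the two-sided Welch
t-test (via `stats::t.test`) with pooled-SD Cohen's
$d = (\bar m_a - \bar m_b)/\sqrt{(s_a^2+s_b^2)/2}$; proportion
comparisons pool counts across players and use the uncorrected 1-df
Pearson χ² (via `stats::chisq.test`). No multiple-testing correction is
applied.

## Mindset classification

A record's log-likelihood under a candidate model is the sum over steps
of the log softmax probability of the recorded action given the recorded
state — action probabilities only, restricted and renormalized to the
actions available in that state. β is a nuisance parameter at
classification time, handled by profile likelihood: each model's
log-likelihood is maximized over a log-spaced grid (an oracle-β mode
that evaluates at the generating β is available for sensitivity
analysis). The predicted mindset is the argmax; exact ties — possible
in principle, vanishingly rare in practice — classify as fixed,
deterministically, and are tallied. Refining the grid can only increase
a maximized likelihood, which the tests assert.

## What the generator emulates, and what it does not

The synthetic cohorts emulate the study conditions: paired β draws,
independently seeded episodes, STOP- or cap-terminated records, and all
group analyses downstream. Passing tests show that the *models* produce
the theorized behavioral contrasts and that the classifier recovers the
generating model well above chance; they do not show anything about
human play. Real players differ in ways the generator does not touch:
individual villagers with personalities (here abstracted to age
classes), richer dialog with multi-utterance surface forms, response
categories beyond a binary reaction (the "correction" response is
reserved but unused), and within-person variation in β across a session.

## Numerical and degenerate-input choices

Softmax probabilities and state values use max-shift stabilization, so
β up to the hundreds is safe. Zero-probability branches are dropped at
model-build time; transition rows are validated to sum to 1 within 1e-9.
A record containing an action impossible under the evaluating model gets
log-likelihood −∞ and is eliminated from that model's side of the
comparison (both sides −∞ is reported as unclassifiable). Empty records
have log-likelihood 0 and no conversations; proportion tests refuse
degenerate 2×2 margins; Welch comparisons refuse two zero-variance
groups. The per-record seed derivation is a small multiplicative-
congruential mix kept strictly below 2³¹.

## Scale and runtime

The test suite and the worked analyses run at the scaled study
conditions — 50 players per mindset × 20 records each (2,000 episodes),
master seed 42 — which take under a minute end to end including both
16,000-state solves and classification of every record; the full
500 × 100 design is a configuration flag (`full_scale = TRUE`) and
scales linearly (~50×).

## Known limitations

* At the scaled conditions the malleable–fixed contrast in *dialog turns
  per conversation* is a statistical tie (difference ~0.02 turns, sign
  unstable across master seeds) even though the conversations-per-game
  contrast is large and stable. The lumpy belief-band rewards make
  breadth (a fresh class at certainty-gain 0.95 per greet) at least as
  attractive per move as depth (asks at gain 0.45 at $|b|=1$), so
  near-optimal malleable play spreads its dialog across more
  conversations rather than deeper ones. A depth-favoring contrast
  evidently requires environment dynamics (e.g. much lower reveal
  probabilities) outside this package's defaults.
* The true norm enters the real-world model only through greet/ask
  reactions; there is no passive observation channel.
* The classifier compares exactly the two shipped profiles; it does not
  estimate a continuum of mindsets.
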