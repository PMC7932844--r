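---
title: "Methods: models, calibration, and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration, and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoperf)
```

This vignette documents the statistical models implemented in
`chronoperf`, the design of the synthetic cohort generator and what it
does and does not emulate, and the numerical conventions the pipeline
commits to — with the reasoning behind each choice.

## 1. Study shape and scoring model

The package targets longitudinal in-the-wild studies in which each
participant completes several short task batteries per day over a few
weeks while wearing a consumer tracker. A battery pairs a psychomotor
vigilance test (PVT) with a fixed-duration addition test (ADD). The
session outcomes are the **median response time** (MRT, milliseconds,
false-start stimuli excluded) and the **number of additions attempted**
(NAA).

Absolute performance is dominated by stable between-person differences,
so the scientific quantities are *relative* scores against each
participant's own baseline:

$$RRT_{s,p} = \left(1 - \frac{MRT_{s,p}}{\overline{MRT}_p}\right)\times 100,
\qquad
RAA_{s,p} = \left(\frac{NAA_{s,p}}{\overline{NAA}_p} - 1\right)\times 100,$$

where the baselines are means over the participant's *retained*
sessions. Both scores increase with better performance, and both have
exactly zero mean per participant — an identity the test suite asserts
to 1e-9, because it silently breaks whenever a filter is applied after
the baseline is computed instead of before.

Retention filters, in order: (1) the chronologically first battery is a
familiarisation instance and is dropped; (2) PVT sessions with MRT
strictly above 800 ms are dropped as inattentive; (3) sessions farther
than 3 SD from the mean of the *survivors* are dropped. The SD rule
uses the population SD (`ddof = 0`) by default — at a few dozen
sessions per participant the difference from the sample SD is immaterial,
but a convention must be fixed for reproducibility; a `sd_type`
switch exposes the alternative. Both threshold rules are
*strictly greater*: a session at exactly 800 ms or exactly 3 SD is
retained. Participants with fewer than 42 completed batteries (one per
day over six weeks, counted before session filters) are excluded
entirely.

Daily analyses use the median of a day's retained sessions, expressed
relative to the across-days mean of those medians with the same
functional forms.

## 2. Chronotype, sleep debt, sleep shift

A **night** is the longest sleep session per (participant, wake date),
where the wake date is the calendar date of the session's end; shorter
same-date sessions are treated as naps. Mid-sleep is the clock time of
the midpoint of the session interval.

Chronotype is the corrected mid-sleep on free days:

$$MSF = MSF_{uc} - 0.5\left(SD_f - \frac{N_w SD_w + N_f SD_f}{N_w+N_f}\right),$$

with $MSF_{uc}$ the average free-night mid-sleep, $SD_w, SD_f$ the mean
sleep durations on work/free days and $N_w, N_f$ their counts. The
correction removes free-day oversleep that compensates work-week debt.
$MSF_{uc}$ is a **circular mean** by default: clock times live on a
24 h circle, and a linear average of, say, 23:30 and 00:30 would give
noon. A `mean_method = "linear"` switch provides the naive mean
anchored at 12:00 for comparison with pipelines that used it; for
participants whose free-night mid-sleeps all fall on one side of noon
the two agree exactly.

**Sleep need** is the overall mean nightly duration (the
duration-weighted work/free combination reduces to the plain mean), and
nightly **sleep debt** is $1 - duration/SN$, which averages to exactly
zero over the nights entering $SN$ — a second identity under test.

**Sleep shift** is the signed difference in minutes between a night's
actual mid-sleep instant and the MSF instant expected for its wake date.
The reference instant is anchored by the wake date (an MSF before noon
falls in the early morning of the wake date, a later one on the evening
before) rather than taken as a minimal circular difference. The
circular alternative could never exceed ±12 h and would fold a rotating
shift worker's 10-hour displacement onto a small value of the wrong
sign; the anchored definition keeps such displacements legible.

Weekly aggregates average the seven nights whose wake dates end at a
given date. A missing night is imputed, metric by metric, with the
running mean of the participant's recorded nights strictly before it —
strictly before, so that imputation never leaks future sleep into a
window and the pipeline is usable in an online setting.

## 3. Momentary features and linkage

Each task is linked to the most recent sleep session that ended before
it, within a 36-hour horizon. The horizon must exceed 24 h or a single
skipped night would unlink an entire day; 36 h keeps a task on the
morning after a missed night linked to the night before while refusing
links so stale they are physiologically meaningless. Time since waking
is the task timestamp minus the linked wake.

Windowed stream statistics use **half-open windows** $(t-w, t]$: the
task minute is included, the minute exactly $w$ earlier is not, so the
10- and 60-minute windows tile without double counting. Windows with
under 50% of their minutes present yield missing values rather than
estimates from a handful of points. Variances are population variances
to match the SD convention above. The "current" heart rate is the
sample at the task's minute, falling back to the nearest sample within
5 minutes.

## 4. Repeated-measures correlation

`rmcorr()` estimates the common within-subject association between two
repeatedly measured variables by ANCOVA: $y$ on a subject factor plus a
single shared slope for $x$. With within-subject centered variables
$\tilde x, \tilde y$:

$$b = \frac{\sum \tilde x \tilde y}{\sum \tilde x^2},\qquad
r_{rm} = \mathrm{sign}(b)\sqrt{\frac{SS_{slope}}{SS_{slope}+SS_{error}}},
\qquad df = N - k - 1,$$

with the p-value from $F(1, df)$ and a Fisher-z interval with
$SE = 1/\sqrt{df-1}$. Subjects contribute only if they have at least
two complete pairs; a subject whose $x$ is constant contributes nothing
to the slope but keeps its $y$ deviations in the error term, exactly as
the explicit dummy-coded regression does.

The estimator matters because aggregating repeated measures and
correlating across subjects can reverse the within-subject association
(Simpson's paradox); the unit tests include a two-subject construction
where the pooled Pearson correlation is negative while $r_{rm} = 0.87$.

Because the centering route is easy to get subtly wrong, the package
ships an independent **oracle**, `rmcorr_oracle()`, which builds the
dummy-coded design matrix explicitly and derives the same quantities
from the sum-of-squares decomposition. The acceptance suite requires
agreement to 1e-10 across randomized cases including missing data and
constant-$x$ subjects, and checks the F test's size (rejection rate
within 3 SE of 0.05 over 2000 null replicates at 16 × 30).

## 5. Cosinor model

`cosinor()` fits the fixed-period sinusoid
$y = M + A\cos(\omega(t-\phi))$, $\omega = 2\pi/period$, through its
linearisation $y = M + \beta_1\cos\omega t + \beta_2\sin\omega t$,
solved by QR least squares (period fixed at 24 h by default — the
rhythm of interest is circadian, and freeing the period on six weeks of
irregularly sampled data mostly fits sampling artefacts). Amplitude is
$\sqrt{\beta_1^2+\beta_2^2}$; the acrophase
$\phi = \mathrm{atan2}(\beta_2,\beta_1)/\omega$ wrapped onto [0, 24).
The acrophase interval comes from the delta method on
$(\beta_1,\beta_2)$ with $t_{n-3}$ critical values; the zero-amplitude
test is the 2-df F test of $\beta_1=\beta_2=0$ — amplitude is not a
linear parameter, so testing it as one coefficient would be wrong.
Acceptance requires exact recovery on noiseless data and acrophase CI
coverage within 3 SE of 95% over 500 replicates. Fits are refused when
fewer than four distinct time points exist or the design is rank
deficient, since three parameters on degenerate phase support are
unidentifiable.

The same machinery runs on clock time and on internal time
$InT = ExT - MSF$; internal time aligns participants by circadian
phase, so acrophases estimated on it are comparable across chronotypes.

## 6. The synthetic cohort generator

`simulate_cohort()` exists for two reasons: the pipeline must be
testable end to end without human data, and power/recovery claims need
a ground truth. It draws three population groups — regular Monday-to-
Friday workers, students with irregular free days, and rotating shift
workers on an 8-day day/day/evening/evening/night/night/off/off cycle —
because the chronobiological metrics are only stressed when sleep
displacement actually occurs (a shift worker's day sleep exercises the
anchored sleep-shift definition, midnight-crossing logic and linkage in
ways regular sleepers never do).

Task outcomes follow a **two-process model**: a circadian component
$C = A\cos(2\pi(InT - 13.5)/24)$ peaking 13.5 h after the individual's
true MSF (late afternoon for an average chronotype), and a homeostatic
pressure that builds during wakefulness as
$1-(1-s_0)e^{-t/\tau_w}$ ($\tau_w = 18.2$ h) and decays during sleep as
$s_0 e^{-t/\tau_s}$ ($\tau_s = 4.2$ h), carried across nights so that a
short night leaves elevated pressure the next day. Configurable
couplings (percent score per SD of the feature) connect sleep duration,
REM/light duration, sleep shift, wake time, time since waking, and
recent heart rate/activity to latent alertness and throughput, which
map to session outcomes through $MRT = m_0(1-alert/100)$ and
$NAA = \mathrm{round}(n_0(1+thr/100))$, with per-stimulus PVT responses
drawn around the session MRT.

The default sleep distribution is calibrated so that, at study scale
(16 participants × 42 nights), pooled mean nightly duration lands near
433 minutes (work nights ~425, free nights ~455, ~27% free days) and
stage composition near 18% REM / 53% light / 16% deep of session time
with the awake remainder. The acceptance suite asserts these moments
within sampling tolerance (±10 min, ±2 percentage points), and
`scripts/acceptance.R` reports them for any seed.

What the generator deliberately does **not** emulate: device-specific
artefacts (heart-rate dropouts during high acceleration, stage
relabeling), naps as a separate process, weekend social events,
caffeine/alcohol effects (a caffeine indicator is emitted but inert),
and learning curves beyond the discarded familiarisation session.
Missingness (night drops, stream gaps) is off by default and opt-in,
so that identities which hold exactly on complete data are tested
exactly, with missingness introduced deliberately where it is the thing
under test.

### A note on analysis levels for coupling recovery

The acceptance suite requires every configured coupling's sign to be
recovered with ≥ 80% power across seeds at 16 × 42 scale. Couplings on
nightly totals (duration, REM, light) are recovered at the **daily**
level, where the median over a day's sessions suppresses session noise.
Couplings on sleep *timing* (sleep shift, wake time) and on momentary
state (time since waking, heart rate, activity) are recovered at the
**session** level through the previous-sleep linkage. The daily route is
unsuitable for timing couplings in a cohort containing displaced
sleepers: joining "the night whose wake date is D" to "the tasks of
calendar date D" misattributes post-midnight tasks and splits a day
sleeper's waking period across two calendar dates, diluting exactly the
nights that carry most of the timing signal. This is a property of
calendar-date aggregation itself, not of the estimator — worth knowing
when analysing real shift-worker data.

## 7. Numerical and engineering conventions

* All timestamps are naive local times at minute resolution (consumer
  exports carry no timezone); internally they are `POSIXct` in UTC so
  daylight-saving arithmetic can never corrupt an interval.
* Clock arithmetic wraps onto [0, 24); `hh:mm` rendering floors to the
  whole minute (10.4 h → `10:24`).
* Population SD/variance throughout, with `sample` switches where a
  user may need to match other software.
* The generator is bit-for-bit reproducible given (configuration,
  seed, component flags); all stochastic acceptance checks state their
  tolerance in SE units of the replicate count.
* Problem sizes: the acceptance suite simulates at full study scale
  (16 × 42, ~670 nights, ~1800 tasks, ~1M stream minutes when streams
  are on); unit tests run on purpose-built miniatures with
  hand-computable answers.
* The pipeline is exposed as ordinary R functions
  (`simulate_cohort()`, `run_analysis()`, the readers/writers) plus the
  `scripts/acceptance.R` entry point, rather than a separate
  command-line binary; an R package's natural composition surface is
  the function, and the script shows the canonical invocation.

## 8. Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(
  sim_config(n_regular = 3, n_shift = 2, n_student = 2, days = 28),
  seed = 42)
analysis <- run_analysis(cohort$tasks, cohort$sleep, cohort$schedule,
                         minutes = cohort$minutes,
                         config = analysis_config(min_tasks = 28))
analysis$sleep_table
analysis$cosinor_table
with(subset(analysis$scores, retained_pvt), cosinor(internal_time, rrt))
```

With all default couplings active, the fitted internal-time acrophase of
alertness falls in the late morning rather than at the pure circadian
peak (MSF + 13.5 h): rising homeostatic pressure pulls the combined
best-time-of-day earlier than the circadian component alone. The
generator's `truth` table separates $C$, $H$ and the couplings per task
for exactly this kind of decomposition.
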