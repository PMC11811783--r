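---
title: "Methods: weekday-aligned k-NN imputation of daily drinking timelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weekday-aligned k-NN imputation of daily drinking timelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlfbknn)
```

## The problem

Timeline Followback (TLFB) interviews reconstruct a daily drinking record
retrospectively: at each antenatal visit a woman reports her most recent
drinking day and the days around it. Days that fall between reporting windows
are never asked about, so the resulting pregnancy timeline — here indexed by
gestational day $-15$ to $310$ relative to the last menstrual period (326
positions) — has long unobserved stretches. The missingness is *informative*:
a woman who drank recently before a visit has a reporting window anchored to
that drinking day, while earlier stretches of her timeline go unrecorded, so
heavier or more recent drinkers are systematically less completely observed.

Simple fixes are poor here. Deleting incomplete subjects discards most of a
cohort and selects against drinkers; filling with per-day column means erases
exactly the structure of interest (episodic, weekend-heavy drinking
concentrated in early pregnancy).

## The imputation model

Each missing gap is filled from similar stretches of other pregnancies. The
key assumptions, each reflected in one mechanism:

1. **Drinking is weekday-patterned.** Candidate donor segments must start on
   the same weekday as the query window, so Saturdays are predicted from
   Saturdays. Two subjects' timelines can be aligned explicitly with
   `align()`: if p's day $-15$ is a Wednesday and q's a Monday, p's day
   $-15$ is compared with q's day $-13$, the nearest later Monday-aligned
   match.
2. **Drinking level varies more across women than within a woman's pattern.**
   Similarity is *cosine* similarity — blind to overall level — computed over
   the positions observed in the query window. A level correction is applied
   afterwards: each donor's values are multiplied by the ratio of the query's
   Euclidean norm to the donor's over the shared observed positions, so a
   light drinker matched to a heavy drinker's pattern is predicted at her own
   level.
3. **Local context predicts the gap.** An `L`-day window (default 55) is
   centred on the gap (shifted to stay in range and to maximise observed
   context); the observed days inside it are the matching context. Donors are
   all gap-free `L`-day segments from the whole cohort, including elsewhere
   in the query subject's own timeline (never a segment overlapping the gap
   being filled).
4. **Drinking trends across pregnancy.** Donor segments must start within
   `position_tolerance` days (default 28) of the query window, so trimester-1
   gaps are filled from trimester-1 behaviour.

The prediction for each missing day is the similarity-weighted mean of the
`k` (default 5) best donors' scaled values, clipped to the site cap. Gaps
longer than `L - min_overlap` days are filled in left-to-right chunks, each
chunk using earlier imputed days as (provenance-flagged) context.

### Zero conventions

Abstinence is a signal, not an absence of signal. Two all-zero contexts get
cosine similarity 1 (an abstinent stretch is a perfect match for another);
one zero against a nonzero context gets similarity 0. When every retained
donor has similarity 0, weights fall back to uniform. A donor whose overlap
norm is 0 keeps scale 1 (no level correction is estimable). If *no* donor
passes the filters (same start weekday, position tolerance, gap coverage,
`min_overlap` observed shared days, default 7), the gap is left missing and
reported — the method never invents values without evidence.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `k` | 5 | Validation sweet spot: averaging across 5 donors beats a single donor on drinking segments, while staying local. |
| `L` | 55 | Trade-off between context (longer windows match more specifically) and pool size (a fully observed timeline yields $327 - L$ segments, so large `L` starves the pool; see `segments_curve()`). |
| `min_overlap` | 7 | At least one full week of shared observed context, so weekday structure can inform the match. |
| `position_tolerance` | 28 | About one gestational month; `"unbounded"` disables the restriction. |
| `classify_threshold` | 0.5 | A predicted segment counts as drinking if its imputed total reaches half a standard drink. |
| caps | SA 21, NP 28 | Site-specific Winsorization of implausible daily totals; `"auto"` uses mean + 3 SD of observed drinking-day values per site. |

Cohort exclusions mirror the intended analysis population: subjects with no
observed trimester-1 day (days 1–93) or more than 200 missing days are set
aside before imputation.

## Validation design

`run_validation()` measures performance where truth is known: it samples
subjects fully observed in trimester 1 (where drinking prevalence and
quantity peak), deletes a uniformly random run of 5–15 consecutive days,
imputes it back, and compares with the held-out truth. Reported per trial:
RMSE over the deleted run, the total-drinks difference, the per-day mean
absolute difference, and drinker/nondrinker classification of the deleted
segment (truth: any drinking day; prediction: imputed total at or above the
threshold). The same deletion is reused for every `k` in the sweep, so
comparisons across `k` are paired, and a per-day column-mean baseline is
recorded alongside. Summaries include percentile intervals of the total
difference and row-normalised confusion matrices.

## The synthetic cohort generator

Because real TLFB records are sensitive, the package ships a generator whose
*realism choices were fixed up front* to emulate the study conditions the
imputer assumes, not tuned to flatter it:

- **Behaviour classes.** Abstainers, quitters (stop at pregnancy
  recognition, uniform day 30–90), reducers (damp rate and amount to 0.35),
  and persistent drinkers, with site-specific mixes: site "SA" has fewer
  abstainers and heavier drinking; "NP" more abstainers and lighter drinking.
- **Subject-level heterogeneity.** Per-subject lognormal multipliers on
  drinking level (`level_sdlog` 0.5) and frequency (`freq_sdlog` 0.3): the
  across-women level spread is what the scaling adjustment targets.
- **Habitual weekday profiles.** The cohort weekday multipliers (weekend
  heavy: Friday/Saturday 1.6/2.4 against 0.4 Monday) are jittered per subject
  (`habit_sdlog` 0.8, renormalised to preserve her overall rate), so each
  drinker concentrates on *her own* habitual days — the subject-specific
  pattern that weekday-aligned matching exploits.
- **Informative missingness.** Observation is mechanistic, not random: the
  enrollment interview covers days $-15$ to $15$; each visit covers the 30
  days ending at the last drinking day before it, through the visit day;
  delivery closes the series at day 310. Abstainers come out fully observed;
  recent drinkers accumulate unreported stretches. Enrollment timing (SA
  late, day 60–140; NP early, 15–70) and variable inter-visit gaps reproduce
  site differences in trimester-1 coverage.

At the default sizes used in the package's own experiments (500 subjects,
100 deletion iterations — chosen to run in seconds while leaving hundreds of
trials per class), a seed-1 cohort shows roughly 13% of person-days missing,
about half of subjects complete, and about 62% drinkers.

What passing on synthetic data shows — and what it does not: recovering
planted scaled twins exactly, matching brute-force neighbour rankings, and
reproducing the qualitative shape of the `k` sweep demonstrate that the
*mechanism* is implemented correctly and behaves as designed when its
assumptions hold. It does not certify accuracy on real cohorts, where the
generative process is unknown.

## A limitation worth stating plainly

Under this generator, mean RMSE on drinking segments for k-NN at $k = 5$
does *not* beat the per-day column-mean baseline. The reason is structural,
not a bug: validation requires subjects fully observed in trimester 1, and
the informative missingness mechanism grants complete trimester-1 coverage
mostly to light, episodic drinkers. For a sparse, spiky daily series, a flat
small mean is a strong RMSE hedge — it is wrong everywhere by a little, while
a pattern-faithful prediction pays quadratically whenever a predicted spike
misses by a day. An oracle given each subject's true per-weekday conditional
means barely outperforms the flat baseline on the same trials. RMSE on
spiky, zero-inflated series rewards blurring; the k-NN imputer is preferable
on the criteria that motivated it — preserving drinking pattern, level, and
drinker classification — rather than on pointwise squared error against a
smoothed baseline.

## Reproducing the numbers

```{r, eval = FALSE}
set.seed(1)
sa <- simulate_cohort(generator_config(250, "SA"))
np <- simulate_cohort(generator_config(250, "NP"))
cohort <- apply_exclusions(winsorize(c(sa$observed, np$observed)))$kept
report <- run_validation(cohort, imputation_config(),
                         k_list = 1:10, iterations = 100)
summary(report)
```

The same experiment is exercised by the test suite, and
`scripts/acceptance.R` recomputes the package's worked-example target from a
fresh install.
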