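---
title: "Contrasting-groups cut scores for electronic kick-impact scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrasting-groups cut scores for electronic kick-impact scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kickcut)
```

## The problem

Electronic taekwondo body protectors (PSS) auto-score a trunk kick when its
registered impact reaches a threshold level set per gender and weight class by
the certifying federation (World Taekwondo). Those thresholds — the "A"
column of the certified table, e.g. 18 levels for men under 58 kg, 25 for men
over 80 kg — were set by expert judgment, not data. `kickcut` implements the
empirical alternative: the *reference-group* (contrasting-groups)
standard-setting method, which derives a threshold from the impact
distributions of a criterion-meeting and a criterion-failing group.

Two contrasts are supported, mirroring how such analyses are run on
competition data:

* **winner vs non-winner** within each gender-by-class stratum: the match
  winner's kicks form the criterion group, the loser's the contrast group;
* **adjacent weight classes**: each class against the next heavier one, the
  heavier class as criterion group, in ascending order (U58–U63, U63–U68,
  U68–U80, U80–O80 for men; U49–U53, U53–U57, U57–U67, U67–O67 for women).

## The model

Each group's impacts are summarized by $(n, \mu, \sigma)$ — arithmetic mean
and sample standard deviation ($n-1$ denominator, the convention behind
"M ± SD" tables) — and treated as $\mathcal N(\mu, \sigma^2)$. The continuous
cutoff $B$ is the point where the two densities are equal. Equating
$\phi(x;\mu_1,\sigma_1) = \phi(x;\mu_2,\sigma_2)$ gives, for
$\sigma_1 \ne \sigma_2$, the quadratic

$$(\sigma_1^2-\sigma_2^2)\,x^2 \;-\; 2(\sigma_1^2\mu_2-\sigma_2^2\mu_1)\,x
\;+\; \sigma_1^2\mu_2^2-\sigma_2^2\mu_1^2
\;-\; 2\sigma_1^2\sigma_2^2\ln(\sigma_1/\sigma_2) \;=\; 0,$$

whose root strictly between the means is the cutoff (the second crossing sits
in a tail and is reported in `all_roots` but never selected). For equal
standard deviations (relative tolerance $10^{-12}$) the cutoff is exactly the
mean midpoint. The quadratic solve uses the numerically stable formulation
and two Newton polish steps on the log-density difference; the returned
cutoff satisfies density equality to $10^{-9}$ relative. A brute-force grid
search (`intersection_oracle`) exists purely as an independent oracle for the
tests.

### When no crossing lies between the means

For unequal variances a crossing strictly between the means exists only when
each density dominates at its own mean, roughly
$|\ln(\sigma_1/\sigma_2)| < \Delta^2 / (2\sigma^2)$ for mean gap $\Delta$.
Close groups with noticeably different spreads violate this: the smaller-sd
density lies above the other across the whole interval. This is not a corner
case here — the winner/non-winner generator imposes a pure mean shift, so the
two groups' population sds are equal and their *sample* sds differ only by
noise, which puts many strata on the wrong side of the inequality. Notably,
the published adjacent-class cutoffs are themselves reproducible as plain
midpoints of the two classes' printed overall means (truncated to one
decimal), i.e. the original analysis effectively used the equal-variance
solution throughout. `gaussian_intersection()` therefore keeps the strict
"unique root between the means, else error" contract by default, and offers
`fallback = "midpoint"`, which the pipeline uses: when no crossing exists
between the means, the cutoff degrades to the equal-variance midpoint and the
solution is labelled `equal_variance_midpoint`.

## Validation and level selection

Thresholds are integers, so candidate levels are the $2w+1$ consecutive
integers centred at the half-up rounding of $B$ (default $w=1$, three
candidates, the window published tables use), clipped below at level 1. At
each candidate $c$ the rule "impact $\ge c$ is criterion-group" is scored:

* **empirical** indices count the actual impacts: accuracy
  $(TP+TN)/N$, sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$;
* **model** indices use the fitted normals: sensitivity
  $1-\Phi((c-\mu_1)/\sigma_1)$, specificity $\Phi((c-\mu_2)/\sigma_2)$,
  accuracy their $n$-weighted mean.

Both definitions are exposed with an explicit `basis` because the validity
indices printed in the source tables (values like 0.365) are not reproducible
from any standard definition without the undeposited raw data; no attempt is
made to reverse-engineer that index.

`select_level()` picks the candidate maximizing accuracy; exact accuracy ties
go to the larger sensitivity (the published heavyweight case: two levels tied
at 0.496, sensitivities 0.674 vs 0.689, the higher-sensitivity level wins);
any remaining tie goes to the *lower* level — the conservative direction,
since over-high thresholds suppress scoring — and `tie_broken` flags that a
tie-break was exercised. Missing sensitivities never win a tie.

The selected level and continuous cutoff are compared with the certified
level A as `gap = |A − B|` with a direction (`wt_higher` / `wt_lower` /
`equal`).

## The synthetic world

Raw per-kick competition exports are not redistributable, so
`default_spec()` states a fixed synthetic world built from published
statistics of a full continental-games tournament:

* per gender, class and hit type, stratum (mean, sd) equal the published
  descriptive table — e.g. men U58 scoring hits 24.6 ± 7.17 levels,
  effective hits 13.6 ± 1.88;
* per-gender registered-hit totals (men: 814 scoring + 1430 effective;
  women: 650 + 688) are apportioned across classes proportionally to the
  published match counts (largest-remainder, totals conserved exactly);
* each cell splits between winner and non-winner roles (winner takes the odd
  kick), and the winner/non-winner contrast is imposed as a configurable mean
  shift, default **+2.0 levels** — the source never prints winning-group
  statistics, and +2 produces the heavily overlapping distributions its
  histograms show; `perturb_spec()` changes the shift (strata store base
  means, so the setter is idempotent);
* impacts are truncated-normal on **(1, 60)** levels via rejection sampling
  (bounds are ≥ 2 sd from every stated mean, so acceptance is high and the
  target shape is exact); generation errors out if bounds would exclude
  more than 99% of a stratum's mass;
* one RNG stream, seeded once (default seed 20180818), drawn in declared
  stratum order — output is byte-identical for identical (spec, seed);
* match ids cycle through the published per-class match counts (104 men's
  and 84 women's matches), so composition summaries reproduce the published
  share table.

What the generator does **not** emulate: the right-skew visible in real
impact histograms (strata are symmetric truncated normals), bout-level
dynamics (rounds, penalties, defended kicks), and any dependence between
kicks of one athlete. A green pipeline test therefore establishes that the
procedure is implemented correctly and is consistent on data satisfying its
own normality assumption — not that the published threshold magnitudes are
recoverable, which they are not without the raw data.

## Numerical choices and edge cases

* Impacts are stored as reals; only the simulator offers integer rounding
  (half-up), since the published group means are decimal and the raw
  quantization is unstated.
* Percent shares round half-up to one decimal, matching printed style; the
  one printed cell that was fudged to make a column sum to 100 (a 19.1 that
  computes to 19.0) is computed, not replicated.
* Equal group means abort with "groups not separable" (no intersection);
  groups with fewer than 2 values or zero variance abort (sd undefined /
  degenerate).
* CSV impacts serialize at 17 significant digits so write-then-read is an
  exact identity.
* Threshold configs are JSON (no YAML parser in the supported dependency
  set); partial configs override per stratum and keep bundled defaults
  elsewhere.
* In the adjacent-classes scheme the heavier class's certified level anchors
  the A-vs-B comparison (the criterion group's threshold); the source never
  states which of the pair's two levels it compared against.

## Worked example

```{r example}
spec <- default_spec()
dataset <- generate_dataset(spec)
report <- run_analysis(dataset, scheme = "win_vs_nonwin")
cat(render_report(report, "text"))
```

And the published-numbers path, which needs no simulation: applying the
selection rule to the bundled published candidate tables reproduces the
published picks, including the sensitivity tie-break:

```{r published}
pub <- published_candidates("win_vs_nonwin")
o80 <- pub[pub$gender == "men" & pub$stratum == "O80", ]
select_level(o80[, c("level", "accuracy", "sensitivity")])
```

## Limitations

The published per-stratum validity magnitudes and the winner/non-winner
continuous cutoffs cannot be recomputed (raw data unavailable; index
definition unstated); this package reproduces the *procedure* and the
worked-example arithmetic that is computable from printed numbers. The
normality assumption is taken as given, as in the source method; no ROC
machinery or bootstrap intervals are provided.
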