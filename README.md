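# kickcut

Contrasting-groups cut-score estimation for electronic kick-impact scoring
systems.

In taekwondo, the electronic body protector (PSS) auto-scores a trunk kick
when its registered impact reaches a threshold *level* fixed per gender and
weight class by the certifying federation (World Taekwondo) — e.g. 18 levels
for men under 58 kg, 25 for men over 80 kg. Those certified levels (column
"A") rest on expert judgment. `kickcut` is for sports scientists and
standard-setting analysts who want the empirical alternative: the
**reference-group (contrasting-groups) model**, which derives a threshold
from data by contrasting a criterion-meeting group with a criterion-failing
group.

## Method

For two groups with fitted normal impact distributions
$\mathcal N(\mu_1,\sigma_1^2)$ (criterion: match winners, or the heavier of
two adjacent classes) and $\mathcal N(\mu_2,\sigma_2^2)$ (contrast), the
continuous cutoff $B$ is the intersection of the two densities — for
$\sigma_1\neq\sigma_2$ the root of

$$(\sigma_1^2-\sigma_2^2)x^2 - 2(\sigma_1^2\mu_2-\sigma_2^2\mu_1)x +
\sigma_1^2\mu_2^2-\sigma_2^2\mu_1^2 - 2\sigma_1^2\sigma_2^2\ln(\sigma_1/\sigma_2)=0$$

lying strictly between the means, and the mean midpoint for equal variances.
Candidate integer levels around $B$ are validated by classification accuracy
(empirical counts or normal-model tails); the selected level maximizes
accuracy, with exact ties broken by higher sensitivity, then by the lower
level. Selected levels and cutoffs are compared against the certified table
as $|A-B|$ gaps with a direction.

Because raw per-kick competition data are not redistributable, the package
includes a seeded stratified truncated-normal simulator whose defaults are
the published descriptive statistics of a full continental-games tournament
(per-class scoring / effective-hit means and sds, match composition, hit
totals), plus the published candidate-validity tables themselves as bundled
inputs. See the vignette `vignettes/reference-group-cutoffs.Rmd` for the
model, assumptions, and design decisions.

## Worked example

```r
library(kickcut)
dataset <- generate_dataset(default_spec())   # seeded synthetic tournament
report  <- run_analysis(dataset, scheme = "win_vs_nonwin")
cat(render_report(report, "text"))
```

prints (actual output, default seed 20180818):

```
Kick-impact scoring standards (win vs nonwin scheme)
Source: synthetic (seed 20180818)

Stratum            A      B  Candidates (level: acc/sens)
men/U58           18   18.8  18: 0.515/0.351  19: 0.485/0.282  20: 0.486/0.266 -> 18 (gap -0.8)
men/U63           20   20.6  20: 0.531/0.381  21: 0.517/0.341  22: 0.520/0.322 -> 20 (gap -0.6)
men/U68           21   20.6  20: 0.534/0.414  21: 0.534/0.383  22: 0.506/0.322 -> 20* (gap 0.4)
men/U80           23   23.0  22: 0.555/0.431  23: 0.543/0.394  24: 0.531/0.352 -> 22 (gap -0.0)
men/O80           25   22.3  21: 0.533/0.450  22: 0.543/0.417  23: 0.523/0.371 -> 22 (gap 2.7)
women/U49         16   17.8  17: 0.525/0.430  18: 0.533/0.398  19: 0.537/0.359 -> 19 (gap -1.8)
women/U53         17   18.1  17: 0.506/0.485  18: 0.498/0.419  19: 0.494/0.382 -> 17 (gap -1.1)
women/U57         18   19.7  19: 0.535/0.408  20: 0.521/0.368  21: 0.521/0.349 -> 19 (gap -1.7)
women/U67         20   20.7  20: 0.498/0.450  21: 0.485/0.408  22: 0.481/0.375 -> 20 (gap -0.7)
women/O67         22   22.4  21: 0.541/0.559  22: 0.522/0.507  23: 0.530/0.493 -> 21 (gap -0.4)

A: certified scoring level; B: continuous contrasting-groups cutoff;
*: accuracy tie resolved by sensitivity (then lower level).
```

Per stratum: `A` is the certified level, `B` the continuous
contrasting-groups cutoff from the synthetic data, each candidate level shows
empirical accuracy/sensitivity, `->` marks the selected level (`*` = accuracy
tie broken by sensitivity), and `gap` is `A - B` — positive where the
certified threshold sits above what the contrast supports.

On the *published* candidate tables (real numbers, no simulation), the
selection rule reproduces the published picks, including the heavyweight
sensitivity tie-break:

```r
pub <- published_candidates("win_vs_nonwin")
o80 <- pub[pub$gender == "men" & pub$stratum == "O80", ]
select_level(o80[, c("level", "accuracy", "sensitivity")])
#> $selected_level
#> [1] 20
#> $tie_broken
#> [1] TRUE
```

(two candidates tied at accuracy 0.496; sensitivities 0.674 vs 0.689 decide
for level 20).

## Command line

```sh
Rscript inst/scripts/kickcut simulate --paper-defaults --seed 7 --out events.csv
Rscript inst/scripts/kickcut analyze --events events.csv --scheme win --format json --out report.json
Rscript inst/scripts/kickcut report --in report.json
```

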