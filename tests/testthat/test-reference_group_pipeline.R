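test_that("split_win_nonwin partitions a stratum by outcome role", {
  d <- impact_dataset(events_df(4))
  g <- split_win_nonwin(d, "men", "U58")
  expect_length(g$hi, 2)
  expect_length(g$lo, 2)

  only_winners <- impact_dataset(events_df(3, athlete_role = "winner"))
  expect_error(split_win_nonwin(only_winners, "men", "U58"), "no 'non_winner'")

  # group sizes on synthetic data equal the spec's stratum n values
  spec <- default_spec()
  ds <- generate_dataset(spec)
  s <- spec$strata
  n_win <- sum(s$n[s$gender == "men" & s$weight_class == "U58" &
                     s$athlete_role == "winner"])
  n_non <- sum(s$n[s$gender == "men" & s$weight_class == "U58" &
                     s$athlete_role == "non_winner"])
  g58 <- split_win_nonwin(ds, "men", "U58")
  expect_length(g58$hi, n_win)
  expect_length(g58$lo, n_non)
  # hit-type filter restricts the pool
  gsc <- split_win_nonwin(ds, "men", "U58", hit_type = "scoring")
  expect_lt(length(gsc$hi), length(g58$hi))
})

test_that("adjacent classes pair in ascending weight order", {
  ds <- generate_dataset(default_spec())
  men <- pair_adjacent_classes(ds, "men")
  expect_length(men, 4)
  expect_identical(vapply(men, `[[`, character(1), "lighter"),
                   c("U58", "U63", "U68", "U80"))
  expect_identical(vapply(men, `[[`, character(1), "heavier"),
                   c("U63", "U68", "U80", "O80"))
  women <- pair_adjacent_classes(ds, "women")
  expect_identical(vapply(women, `[[`, character(1), "lighter"),
                   c("U49", "U53", "U57", "U67"))
  expect_identical(vapply(women, `[[`, character(1), "heavier"),
                   c("U53", "U57", "U67", "O67"))

  no_u68 <- impact_dataset(ds$events[ds$events$weight_class != "U68", ])
  expect_error(pair_adjacent_classes(no_u68, "men"), "U68")
})

test_that("analyze_class recovers an analytic midpoint on separated groups", {
  set.seed(3)
  hi <- rnorm(50000, 20, 2)
  lo <- rnorm(50000, 10, 2)
  res <- analyze_class(hi, lo, wt_level = 18, stratum = "unit")
  expect_lt(abs(res$decision$continuous_cutoff - 15), 0.1)
  expect_gte(res$level_gap, 2)
  expect_equal(res$gap, 18 - res$decision$continuous_cutoff)
  expect_true(res$decision$selected_level %in% res$decision$candidates$level)

  x <- rnorm(100, 15, 2)
  expect_error(analyze_class(x, x, wt_level = 18), "not separable")
})

test_that("selected level equals wt_level gives zero level gap", {
  set.seed(8)
  hi <- rnorm(5000, 20, 2)
  lo <- rnorm(5000, 10, 2)
  res <- analyze_class(hi, lo, wt_level = 15)
  expect_identical(res$level_gap, 15L - res$decision$selected_level)
})

test_that("run_analysis covers every stratum and is deterministic", {
  ds <- generate_dataset(default_spec())
  rep_win <- run_analysis(ds, "win_vs_nonwin")
  expect_length(rep_win$results, 10)
  rep_adj <- run_analysis(ds, "adjacent_classes")
  expect_length(rep_adj$results, 8)
  expect_identical(run_analysis(ds, "win_vs_nonwin"), rep_win)
  # every selected level lies inside its candidate window
  for (r in c(rep_win$results, rep_adj$results)) {
    expect_true(r$decision$selected_level %in%
                  candidate_levels(r$decision$continuous_cutoff, 1))
  }
  # composition summary reflects the generator's match-id structure
  expect_identical(attr(rep_win$composition$men, "total"), 104L)
})

test_that("the estimated cutoff is consistent as per-group n grows", {
  truth <- 15  # equal sds: analytic intersection is the midpoint
  err_at <- function(n, seed) {
    spec <- contrast_spec(n = n, mean = 14, sd = 2.5, winner_shift = 2,
                          seed = seed)
    ev <- generate_dataset(spec)$events
    res <- analyze_class(ev$impact[ev$athlete_role == "winner"],
                         ev$impact[ev$athlete_role == "non_winner"],
                         wt_level = 18)
    abs(res$decision$continuous_cutoff - truth)
  }
  seeds <- 1:20
  err_small <- vapply(seeds, function(s) err_at(100, s), numeric(1))
  err_large <- vapply(seeds, function(s) err_at(10000, s), numeric(1))
  expect_lt(mean(err_large), mean(err_small))
})

test_that("compare_with_wt reports gap magnitude and direction", {
  c1 <- compare_with_wt(18.8, 18)
  expect_equal(c1$gap, 0.8)
  expect_identical(c1$direction, "wt_lower")
  c2 <- compare_with_wt(19.0, 25)
  expect_equal(c2$gap, 6)
  expect_identical(c2$direction, "wt_higher")
  c3 <- compare_with_wt(20, 20)
  expect_equal(c3$gap, 0)
  expect_identical(c3$direction, "equal")
  # direction always agrees with the sign of A - B
  set.seed(2)
  for (i in 1:20) {
    b <- runif(1, 10, 30); a <- sample(10:30, 1)
    cc <- compare_with_wt(b, a)
    expect_identical(cc$direction,
                     if (a > b) "wt_higher" else if (a < b) "wt_lower" else "equal")
    expect_equal(cc$gap, abs(a - b))
  }
})

test_that("descriptive summary mirrors the published-table layout", {
  d <- impact_dataset(events_df(3, hit_type = "scoring",
                                impact = c(24, 25, 26)))
  tab <- descriptive_summary(d)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$scoring_mean, 25)
  expect_equal(tab$scoring_sd, 1)
  # empty effective subgroup is an NA cell, not an error
  expect_true(is.na(tab$effective_mean))
  expect_equal(tab$overall_mean, 25)

  # large-n synthetic cells sit near the published targets
  ds <- generate_dataset(perturb_spec(contrast_spec(
    n = 30000, mean = 24.6, sd = 7.17, seed = 13L), 0))
  big <- descriptive_summary(ds)
  expect_lt(abs(big$scoring_mean - 24.6), 0.3)
  expect_lt(abs(big$scoring_sd - 7.17), 0.3)
})

test_that("published adjacent-pair cutoffs equal the printed mean midpoints", {
  # the published continuous cutoffs for the adjacent-class scheme are the
  # midpoints of the two classes' published overall means, truncated to one
  # decimal -- so B there is recomputable from printed statistics alone
  overall <- c(U58 = 18.4, U63 = 20.6, U68 = 19.7, U80 = 21.4, O80 = 18.7,
               U49 = 16.1, U53 = 16.0, U57 = 19.1, U67 = 17.3, O67 = 17.3)
  pub <- published_candidates("adjacent_classes")
  pairs <- unique(pub[, c("gender", "stratum", "B")])
  for (i in seq_len(nrow(pairs))) {
    cls <- strsplit(pairs$stratum[i], "-")[[1]]
    mid <- mean(overall[cls])
    expect_lt(abs(mid - pairs$B[i]), 0.051)
    expect_equal(trunc(mid * 10) / 10, pairs$B[i])
  }
})

test_that("reports render to text, csv and json with stable content", {
  ds <- generate_dataset(default_spec())
  rep <- run_analysis(ds, "win_vs_nonwin")

  txt <- render_report(rep, "text")
  expect_match(txt, "win vs nonwin")
  expect_match(txt, "men/U58")

  csv <- render_report(rep, "csv")
  parsed <- utils::read.csv(textConnection(csv))
  expect_identical(nrow(parsed), 10L)
  # csv round-trips numerically at full precision
  expect_equal(parsed$continuous_cutoff,
               vapply(rep$results, function(r) r$decision$continuous_cutoff,
                      numeric(1)))

  js <- render_report(rep, "json")
  reparsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(
    as.character(jsonlite::toJSON(reparsed, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE, na = "null")),
    js)
  expect_length(reparsed$results, 10)

  # end-to-end determinism: regenerate and re-render byte-identically
  rep2 <- run_analysis(generate_dataset(default_spec()), "win_vs_nonwin")
  expect_identical(render_report(rep2, "json"), js)

  expect_error(render_report(rep, "xml"), "unknown report format")
})

test_that("the CLI wires simulate -> analyze -> report together", {
  events <- withr::local_tempfile(fileext = ".csv")
  out <- withr::local_tempfile(fileext = ".json")
  expect_identical(
    suppressMessages(kickcut_cli(c("simulate", "--paper-defaults",
                                   "--seed", "77", "--out", events))), 0L)
  expect_true(file.exists(events))
  expect_identical(
    suppressMessages(kickcut_cli(c("analyze", "--events", events,
                                   "--scheme", "win", "--format", "json",
                                   "--out", out))), 0L)
  parsed <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  expect_length(parsed$results, 10)
  txt <- capture.output(suppressMessages(kickcut_cli(c("report", "--in", out))))
  expect_match(paste(txt, collapse = "\n"), "men/U58")
  expect_identical(suppressMessages(kickcut_cli(c("analyze"))), 1L)
})
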