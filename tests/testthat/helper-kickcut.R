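# Shared builders for small fixtures; everything is generated in code.

stratum_row <- function(gender = "men", weight_class = "U58",
                        athlete_role = "winner", hit_type = "scoring",
                        n = 10, mean = 20, sd = 3) {
  data.frame(gender = gender, weight_class = weight_class,
             athlete_role = athlete_role, hit_type = hit_type,
             n = n, mean = mean, sd = sd, stringsAsFactors = FALSE)
}

# one-class winner/non-winner spec with configurable group parameters
contrast_spec <- function(n = 100, mean = 20, sd = 3, winner_shift = 2,
                          seed = 1L, truncation = c(1, 60), ...) {
  simulation_spec(
    rbind(
      stratum_row(athlete_role = "winner", n = n, mean = mean, sd = sd),
      stratum_row(athlete_role = "non_winner", n = n, mean = mean, sd = sd)
    ),
    truncation = truncation, winner_shift = winner_shift, seed = seed, ...
  )
}

events_df <- function(n = 4, gender = "men", weight_class = "U58",
                      athlete_role = rep(c("winner", "non_winner"), length.out = n),
                      hit_type = "scoring",
                      impact = seq(10, by = 2, length.out = n)) {
  data.frame(match_id = sprintf("m%02d", seq_len(n)),
             gender = rep(gender, length.out = n),
             weight_class = rep(weight_class, length.out = n),
             athlete_role = rep(athlete_role, length.out = n),
             hit_type = rep(hit_type, length.out = n),
             impact = rep(impact, length.out = n), stringsAsFactors = FALSE)
}

# published per-gender match counts (composition table)
published_match_counts <- function(gender) {
  switch(gender,
         men   = c(U58 = 24, U63 = 25, U68 = 21, U80 = 20, O80 = 14),
         women = c(U49 = 16, U53 = 17, U57 = 19, U67 = 15, O67 = 17))
}
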