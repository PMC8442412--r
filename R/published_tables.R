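# Bundled published standard-setting tables from the 2018 continental-games
# PSS study: candidate integer levels with their printed classification
# accuracies (and, where printed, sensitivities), per stratum and grouping
# scheme, together with the continuous cutoff B and certified level A.
# The raw per-kick data behind these tables were never deposited; the printed
# candidate indices are therefore inputs, usable to exercise the
# level-selection rule on real published numbers.

#' Published candidate-level validity tables
#'
#' Loads the bundled candidate tables from the published 2018 elite
#' competition standard-setting analysis. For the winner/non-winner scheme
#' each stratum has a certified level `A`, a continuous cutoff `B` and three
#' candidate levels with printed accuracies (sensitivity only where printed);
#' for the adjacent-classes scheme strata are (lighter, heavier) pairs.
#'
#' @param scheme `"win_vs_nonwin"` or `"adjacent_classes"`.
#' @return data.frame with columns `gender`, `stratum`, `A` (win scheme only),
#'   `B`, `level`, `accuracy`, `sensitivity`.
#' @export
published_candidates <- function(scheme = c("win_vs_nonwin", "adjacent_classes")) {
  scheme <- match.arg(scheme)
  file <- switch(scheme,
                 win_vs_nonwin = "published_candidates_winloss.csv",
                 adjacent_classes = "published_candidates_adjacent.csv")
  path <- system.file("extdata", file, package = "kickcut")
  if (!nzchar(path)) stop("bundled table not found: ", file, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
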