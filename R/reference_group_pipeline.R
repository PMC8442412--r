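# Orchestration: the two contrast-group schemes (winner vs non-winner within
# a class; adjacent weight classes), per-stratum cutoff estimation and level
# selection, comparison against the certified threshold table, and reporting.

#' Split one stratum into winner and non-winner impact groups
#'
#' All of an athlete's registered kicks are attributed by that athlete's match
#' outcome role; both hit types are pooled unless `hit_type` filters one.
#'
#' @param dataset an `impact_dataset`.
#' @param gender `"men"` or `"women"`.
#' @param weight_class canonical class code.
#' @param hit_type optional `"scoring"` or `"effective"` filter.
#' @return list with `hi` (winner impacts) and `lo` (non-winner impacts).
#' @export
split_win_nonwin <- function(dataset, gender, weight_class, hit_type = NULL) {
  stopifnot(inherits(dataset, "impact_dataset"))
  gender <- match.arg(gender, .kc_genders)
  weight_class <- match.arg(weight_class, .kc_weight_classes[[gender]])
  ev <- dataset$events
  keep <- ev$gender == gender & ev$weight_class == weight_class
  if (!is.null(hit_type)) {
    keep <- keep & ev$hit_type == match.arg(hit_type, .kc_hit_types)
  }
  ev <- ev[keep, , drop = FALSE]
  if (!nrow(ev)) {
    stop(sprintf("no events for stratum %s/%s", gender, weight_class),
         call. = FALSE)
  }
  for (role in .kc_roles) {
    if (!any(ev$athlete_role == role)) {
      stop(sprintf("stratum %s/%s has no '%s' events", gender, weight_class,
                   role), call. = FALSE)
    }
  }
  list(hi = ev$impact[ev$athlete_role == "winner"],
       lo = ev$impact[ev$athlete_role == "non_winner"])
}

#' Pair adjacent weight classes for one gender
#'
#' Returns the four ordered (lighter, heavier) class pairs in ascending
#' weight order; within a class all athletes' kicks are pooled. The heavier
#' class is treated as the criterion ("hi") group.
#'
#' @param dataset an `impact_dataset`.
#' @param gender `"men"` or `"women"`.
#' @param hit_type optional hit-type filter.
#' @return list of 4 elements: `lighter`, `heavier`, `lo`, `hi`.
#' @export
pair_adjacent_classes <- function(dataset, gender, hit_type = NULL) {
  stopifnot(inherits(dataset, "impact_dataset"))
  gender <- match.arg(gender, .kc_genders)
  classes <- .kc_weight_classes[[gender]]
  ev <- dataset$events[dataset$events$gender == gender, , drop = FALSE]
  if (!is.null(hit_type)) {
    ev <- ev[ev$hit_type == match.arg(hit_type, .kc_hit_types), , drop = FALSE]
  }
  missing <- classes[!(classes %in% ev$weight_class)]
  if (length(missing)) {
    stop(sprintf("missing weight class(es) for %s: %s", gender,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lapply(seq_len(length(classes) - 1), function(k) {
    list(lighter = classes[k], heavier = classes[k + 1],
         lo = ev$impact[ev$weight_class == classes[k]],
         hi = ev$impact[ev$weight_class == classes[k + 1]])
  })
}

#' Analyze one contrast: cutoff, candidates, level, gaps
#'
#' Fits group statistics for the criterion (hi) and contrast (lo) groups,
#' solves the Gaussian intersection, evaluates empirical validity at each
#' candidate integer level, selects a level (accuracy, then sensitivity, then
#' lower level), and records the gaps to the certified level A.
#'
#' @param hi_impacts,lo_impacts raw impact vectors (>= 2 values each).
#' @param wt_level certified integer level A for the stratum.
#' @param window candidate half-width (default 1: three candidate levels).
#' @param stratum label stored in the result (free-form).
#' @return a `class_result` object.
#' @export
analyze_class <- function(hi_impacts, lo_impacts, wt_level, window = 1,
                          stratum = NULL) {
  hi_stats <- fit_group_stats(hi_impacts)
  lo_stats <- fit_group_stats(lo_impacts)
  # midpoint fallback: with near-equal group sds the fitted densities may not
  # cross between the means; the equal-variance midpoint is the degenerate
  # contrasting-groups cutoff there (and matches the published tables)
  sol <- gaussian_intersection(hi_stats, lo_stats, fallback = "midpoint")
  levels <- candidate_levels(sol$cutoff, window)
  idx <- lapply(levels, function(l) empirical_validity(hi_impacts, lo_impacts, l))
  cand <- data.frame(
    level = levels,
    accuracy = vapply(idx, `[[`, numeric(1), "accuracy"),
    sensitivity = vapply(idx, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(idx, `[[`, numeric(1), "specificity")
  )
  sel <- select_level(cand)
  decision <- structure(
    list(continuous_cutoff = sol$cutoff, candidates = cand,
         selected_level = sel$selected_level, tie_broken = sel$tie_broken),
    class = "level_decision"
  )
  structure(
    list(stratum = stratum, hi_stats = hi_stats, lo_stats = lo_stats,
         solution = sol, decision = decision,
         wt_level = as.integer(wt_level),
         gap = wt_level - sol$cutoff,
         level_gap = as.integer(wt_level - sel$selected_level)),
    class = "class_result"
  )
}

#' @export
print.class_result <- function(x, ...) {
  cat(sprintf("<class_result %s: A=%d B=%.1f selected=%d%s gap=%.1f>\n",
              if (is.null(x$stratum)) "" else x$stratum,
              x$wt_level, x$decision$continuous_cutoff,
              x$decision$selected_level,
              if (x$decision$tie_broken) " (tie-broken)" else "",
              x$gap))
  invisible(x)
}

#' Compare a study cutoff B with the certified level A
#'
#' @param b the study's cutoff: a numeric (continuous B) or a
#'   `level_decision` (its continuous cutoff is used).
#' @param wt_level certified integer level A.
#' @return list with `gap` (`|A - B|`) and `direction` (`"wt_higher"`,
#'   `"wt_lower"` or `"equal"` by the sign of A - B).
#' @export
compare_with_wt <- function(b, wt_level) {
  if (inherits(b, "level_decision")) b <- b$continuous_cutoff
  stopifnot(is.numeric(b), length(b) == 1, is.numeric(wt_level))
  diffn <- wt_level - b
  list(gap = abs(diffn),
       direction = if (diffn > 0) "wt_higher"
                   else if (diffn < 0) "wt_lower" else "equal")
}

#' Per-stratum descriptive summary (M +/- SD by hit type)
#'
#' One row per gender-by-class stratum present in the data, with (n, mean,
#' sd) for the scoring group, the effective-hit group, and all hits pooled.
#' Cells whose subgroup has fewer than 2 events are marked unavailable (NA).
#'
#' @param dataset an `impact_dataset`.
#' @return data.frame, one row per stratum.
#' @export
descriptive_summary <- function(dataset) {
  stopifnot(inherits(dataset, "impact_dataset"))
  ev <- dataset$events
  if (!nrow(ev)) stop("empty dataset", call. = FALSE)
  cell <- function(x) {
    if (length(x) < 2) c(n = length(x), mean = NA_real_, sd = NA_real_)
    else c(n = length(x), mean = base::mean(x), sd = stats::sd(x))
  }
  rows <- list()
  for (g in .kc_genders) {
    for (wc in .kc_weight_classes[[g]]) {
      sub <- ev[ev$gender == g & ev$weight_class == wc, , drop = FALSE]
      if (!nrow(sub)) next
      sc <- cell(sub$impact[sub$hit_type == "scoring"])
      ef <- cell(sub$impact[sub$hit_type == "effective"])
      ov <- cell(sub$impact)
      rows[[length(rows) + 1L]] <- data.frame(
        gender = g, weight_class = wc,
        scoring_n = sc[["n"]], scoring_mean = sc[["mean"]], scoring_sd = sc[["sd"]],
        effective_n = ef[["n"]], effective_mean = ef[["mean"]],
        effective_sd = ef[["sd"]],
        overall_n = ov[["n"]], overall_mean = ov[["mean"]], overall_sd = ov[["sd"]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full standard-setting analysis
#'
#' Applies one grouping scheme across every stratum present in the dataset:
#' `"win_vs_nonwin"` contrasts winner vs non-winner kicks within each
#' gender-by-class stratum (10 results on complete data); `"adjacent_classes"`
#' contrasts each class with the next heavier one (8 pairs), with the heavier
#' class as criterion group and its certified level as A.
#'
#' @param dataset an `impact_dataset`.
#' @param scheme `"win_vs_nonwin"` or `"adjacent_classes"`.
#' @param thresholds a `threshold_table` (default: bundled certified levels).
#' @param window candidate half-width.
#' @param hit_type optional hit-type filter (default: pool both).
#' @return an `analysis_report`.
#' @export
run_analysis <- function(dataset, scheme = c("win_vs_nonwin", "adjacent_classes"),
                         thresholds = load_thresholds(), window = 1,
                         hit_type = NULL) {
  stopifnot(inherits(dataset, "impact_dataset"),
            inherits(thresholds, "threshold_table"))
  scheme <- match.arg(scheme)
  ev <- dataset$events
  if (!nrow(ev)) stop("empty dataset", call. = FALSE)
  results <- list()
  if (scheme == "win_vs_nonwin") {
    for (g in .kc_genders) {
      present <- intersect(.kc_weight_classes[[g]], unique(ev$weight_class[ev$gender == g]))
      for (wc in present) {
        groups <- split_win_nonwin(dataset, g, wc, hit_type = hit_type)
        results[[length(results) + 1L]] <- analyze_class(
          groups$hi, groups$lo, wt_level(thresholds, g, wc),
          window = window, stratum = paste(g, wc, sep = "/"))
      }
    }
  } else {
    for (g in .kc_genders) {
      if (!any(ev$gender == g)) next
      pairs <- pair_adjacent_classes(dataset, g, hit_type = hit_type)
      for (p in pairs) {
        results[[length(results) + 1L]] <- analyze_class(
          p$hi, p$lo, wt_level(thresholds, g, p$heavier),
          window = window,
          stratum = paste(g, paste0(p$lighter, "-", p$heavier), sep = "/"))
      }
    }
  }
  comp <- lapply(.kc_genders, function(g) {
    sub <- ev[ev$gender == g, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    counts <- tapply(sub$match_id, sub$weight_class,
                     function(m) length(unique(m)))
    match_share_table(counts, g)
  })
  names(comp) <- .kc_genders
  structure(
    list(scheme = scheme, results = results,
         descriptives = descriptive_summary(dataset),
         composition = comp[!vapply(comp, is.null, logical(1))],
         provenance = dataset$provenance, seed = dataset$seed),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}

.kc_report_rows <- function(report) {
  do.call(rbind, lapply(report$results, function(r) {
    data.frame(
      stratum = r$stratum,
      hi_n = r$hi_stats$n, hi_mean = r$hi_stats$mean, hi_sd = r$hi_stats$sd,
      lo_n = r$lo_stats$n, lo_mean = r$lo_stats$mean, lo_sd = r$lo_stats$sd,
      wt_level = r$wt_level,
      continuous_cutoff = r$decision$continuous_cutoff,
      selected_level = r$decision$selected_level,
      tie_broken = r$decision$tie_broken,
      gap = r$gap, level_gap = r$level_gap,
      stringsAsFactors = FALSE
    )
  }))
}

#' Render an analysis report
#'
#' `"text"` mirrors the printed threshold tables (certified level A,
#' continuous cutoff B, candidate levels with their validity indices);
#' `"csv"` gives one full-precision row per stratum; `"json"` serializes the
#' whole report and re-parses to identical content.
#'
#' @param report an `analysis_report`.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @return a single character string (the file content).
#' @export
render_report <- function(report, format = c("text", "csv", "json")) {
  stopifnot(inherits(report, "analysis_report"))
  if (!is.character(format)) stop("unknown report format", call. = FALSE)
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown report format: ",
                                              format[1], call. = FALSE))
  if (format == "csv") {
    rows <- .kc_report_rows(report)
    for (col in c("hi_mean", "hi_sd", "lo_mean", "lo_sd",
                  "continuous_cutoff", "gap")) {
      rows[[col]] <- sprintf("%.17g", rows[[col]])
    }
    con <- textConnection("csv_out", "w", local = TRUE)
    utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
    close(con)
    return(paste0(paste(csv_out, collapse = "\n"), "\n"))
  }
  if (format == "json") {
    serial <- list(
      scheme = report$scheme,
      provenance = report$provenance,
      seed = if (is.na(report$seed)) NULL else report$seed,
      results = lapply(report$results, function(r) {
        list(stratum = r$stratum,
             hi = unclass(r$hi_stats), lo = unclass(r$lo_stats),
             cutoff_method = r$solution$method,
             continuous_cutoff = r$decision$continuous_cutoff,
             candidates = r$decision$candidates,
             selected_level = r$decision$selected_level,
             tie_broken = r$decision$tie_broken,
             wt_level = r$wt_level, gap = r$gap, level_gap = r$level_gap)
      }),
      descriptives = report$descriptives,
      composition = lapply(report$composition, function(tab) {
        list(table = tab, total = attr(tab, "total"))
      })
    )
    return(as.character(jsonlite::toJSON(serial, auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE,
                                         na = "null")))
  }
  # text
  lines <- c(
    sprintf("Kick-impact scoring standards (%s scheme)",
            gsub("_", " ", report$scheme)),
    sprintf("Source: %s", report$provenance),
    "",
    sprintf("%-16s %3s %6s  %s", "Stratum", "A", "B", "Candidates (level: acc/sens)")
  )
  for (r in report$results) {
    cand <- r$decision$candidates
    cand_txt <- paste(sprintf("%d: %.3f/%.3f", cand$level, cand$accuracy,
                              cand$sensitivity), collapse = "  ")
    lines <- c(lines, sprintf(
      "%-16s %3d %6.1f  %s -> %d%s (gap %.1f)",
      r$stratum, r$wt_level, r$decision$continuous_cutoff, cand_txt,
      r$decision$selected_level,
      if (r$decision$tie_broken) "*" else "", r$gap))
  }
  lines <- c(lines, "",
             "A: certified scoring level; B: continuous contrasting-groups cutoff;",
             "*: accuracy tie resolved by sensitivity (then lower level).")
  paste0(paste(lines, collapse = "\n"), "\n")
}
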