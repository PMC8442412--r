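# Contrasting-groups cut-score core: fit group statistics, intersect two
# normal densities, compute classification validity indices at a cutoff, and
# select an integer scoring level with the sensitivity tie-break.

#' Group summary statistics
#'
#' @param n sample size (>= 2).
#' @param mean group mean impact (levels).
#' @param sd group sample standard deviation (> 0).
#' @return a `group_stats` object.
#' @export
group_stats <- function(n, mean, sd) {
  stopifnot(is.numeric(n), is.numeric(mean), is.numeric(sd))
  if (n < 2) stop("group size must be at least 2", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("group sd must be positive", call. = FALSE)
  structure(list(n = as.integer(n), mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats: n=%d, mean=%.4g, sd=%.4g>\n", x$n, x$mean, x$sd))
  invisible(x)
}

#' Fit group statistics from raw impacts
#'
#' Mean is the arithmetic mean; sd is the sample standard deviation
#' (n - 1 denominator), the convention behind reported "M +/- SD" tables.
#'
#' @param impacts numeric vector, at least 2 values.
#' @return a `group_stats` object.
#' @export
fit_group_stats <- function(impacts) {
  impacts <- as.numeric(impacts)
  if (length(impacts) < 2) {
    stop("need at least 2 impacts to fit group statistics (sd undefined)",
         call. = FALSE)
  }
  if (any(!is.finite(impacts))) stop("impacts must be finite", call. = FALSE)
  s <- stats::sd(impacts)
  if (s == 0) stop("degenerate group: zero variance", call. = FALSE)
  group_stats(length(impacts), base::mean(impacts), s)
}

# Log-density difference g(x) = log phi_hi(x) - log phi_lo(x) and derivative;
# used to polish the quadratic root to machine precision.
.kc_logdens_diff <- function(x, hi, lo) {
  stats::dnorm(x, hi$mean, hi$sd, log = TRUE) -
    stats::dnorm(x, lo$mean, lo$sd, log = TRUE)
}
.kc_logdens_diff_grad <- function(x, hi, lo) {
  -(x - hi$mean) / hi$sd^2 + (x - lo$mean) / lo$sd^2
}

#' Intersection of two normal densities
#'
#' Solves for the point where the two fitted group densities are equal: the
#' contrasting-groups reference point. With equal standard deviations the
#' intersection is the midpoint of the means; otherwise the log-density
#' equation is a quadratic with two roots, of which the one strictly between
#' the two means is the cutoff (the second crossing lies in a tail and is
#' reported in `all_roots` but never selected).
#'
#' When the fitted standard deviations differ while the means are close, the
#' two densities may not cross between the means at all (the smaller-sd
#' density dominates the whole interval); geometrically this happens whenever
#' `|log(sd1/sd2)|` exceeds roughly `gap^2 / (2 sd^2)`. With
#' `fallback = "midpoint"` such cases degrade to the equal-variance solution,
#' the mean midpoint -- which is also what the published threshold tables
#' turn out to use (their printed cutoffs equal the midpoints of the printed
#' group means). The default keeps the strict error contract.
#'
#' @param hi `group_stats` of the criterion-meeting (higher-impact) group.
#' @param lo `group_stats` of the criterion-failing group.
#' @param fallback `"error"` (default) to fail when no crossing lies strictly
#'   between the means, or `"midpoint"` to return the equal-variance midpoint
#'   solution in that case.
#' @return a `cutpoint_solution` with fields `cutoff`, `all_roots`, `method`.
#' @export
gaussian_intersection <- function(hi, lo, fallback = c("error", "midpoint")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(hi, "group_stats"), inherits(lo, "group_stats"))
  m1 <- hi$mean; s1 <- hi$sd
  m2 <- lo$mean; s2 <- lo$sd
  scale <- max(abs(m1), abs(m2), 1)
  if (abs(m1 - m2) <= 1e-12 * scale) {
    stop("groups not separable: equal means", call. = FALSE)
  }
  if (abs(s1 - s2) <= 1e-12 * max(s1, s2)) {
    cutoff <- (m1 + m2) / 2
    return(structure(list(cutoff = cutoff, all_roots = cutoff,
                          method = "equal_variance_midpoint"),
                     class = "cutpoint_solution"))
  }
  # (s1^2 - s2^2) x^2 - 2 (s1^2 m2 - s2^2 m1) x
  #   + s1^2 m2^2 - s2^2 m1^2 - 2 s1^2 s2^2 log(s1/s2) = 0
  a <- s1^2 - s2^2
  b <- -2 * (s1^2 * m2 - s2^2 * m1)
  cc <- s1^2 * m2^2 - s2^2 * m1^2 - 2 * s1^2 * s2^2 * log(s1 / s2)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real intersection found", call. = FALSE)
  # numerically stable quadratic roots
  q <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
  roots <- sort(c(q / a, if (q != 0) cc / q else -b / a - q / a))
  lo_m <- min(m1, m2); hi_m <- max(m1, m2)
  between <- roots[roots > lo_m & roots < hi_m]
  if (length(between) != 1) {
    if (fallback == "midpoint") {
      return(structure(list(cutoff = (m1 + m2) / 2, all_roots = roots,
                            method = "equal_variance_midpoint"),
                       class = "cutpoint_solution"))
    }
    stop("no unique intersection between the group means", call. = FALSE)
  }
  cutoff <- between
  # two Newton polish steps on the log-density difference
  for (k in 1:2) {
    g <- .kc_logdens_diff(cutoff, hi, lo)
    dg <- .kc_logdens_diff_grad(cutoff, hi, lo)
    if (dg != 0) cutoff <- cutoff - g / dg
  }
  d1 <- stats::dnorm(cutoff, m1, s1)
  d2 <- stats::dnorm(cutoff, m2, s2)
  if (abs(d1 - d2) > 1e-9 * max(d1, d2)) {
    stop("density equality not achieved at the computed cutoff", call. = FALSE)
  }
  roots[which.min(abs(roots - cutoff))] <- cutoff
  structure(list(cutoff = cutoff, all_roots = roots, method = "quadratic"),
            class = "cutpoint_solution")
}

#' @export
print.cutpoint_solution <- function(x, ...) {
  cat(sprintf("<cutpoint_solution: cutoff=%.6g (%s)>\n", x$cutoff, x$method))
  invisible(x)
}

#' Brute-force intersection oracle
#'
#' Grid search between the two means for the point of minimum absolute
#' density difference. Independent of [gaussian_intersection()]; used in
#' tests as the reference implementation.
#'
#' @param hi,lo `group_stats` objects with different means.
#' @param step grid step (must be smaller than the mean gap).
#' @return the grid point minimizing `|pdf_hi - pdf_lo|`.
#' @export
intersection_oracle <- function(hi, lo, step = 1e-4) {
  stopifnot(inherits(hi, "group_stats"), inherits(lo, "group_stats"), step > 0)
  lo_m <- min(hi$mean, lo$mean)
  hi_m <- max(hi$mean, lo$mean)
  if (hi_m - lo_m <= 1e-12 * max(abs(hi_m), 1)) {
    stop("groups not separable: equal means", call. = FALSE)
  }
  if (step >= hi_m - lo_m) {
    stop("step must be smaller than the gap between the means", call. = FALSE)
  }
  grid <- seq(lo_m + step, hi_m - step, by = step)
  d <- abs(stats::dnorm(grid, hi$mean, hi$sd) - stats::dnorm(grid, lo$mean, lo$sd))
  grid[which.min(d)]
}

.kc_validity <- function(accuracy, sensitivity, specificity, counts, basis) {
  structure(list(accuracy = accuracy, sensitivity = sensitivity,
                 specificity = specificity, counts = counts, basis = basis),
            class = "validity_indices")
}

#' @export
print.validity_indices <- function(x, ...) {
  cat(sprintf("<validity_indices (%s): acc=%.3f sens=%.3f spec=%.3f>\n",
              x$basis, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Empirical classification validity at a cutoff
#'
#' Counts how well the rule "impact >= cutoff is in the criterion group"
#' classifies the observed impacts: TP/FN from the criterion (hi) group,
#' TN/FP from the contrast (lo) group.
#'
#' @param hi_impacts impacts of the criterion-meeting group.
#' @param lo_impacts impacts of the criterion-failing group.
#' @param cutoff classification threshold (levels).
#' @return a `validity_indices` with `basis = "empirical"` and the
#'   `(TP, FP, TN, FN)` counts.
#' @export
empirical_validity <- function(hi_impacts, lo_impacts, cutoff) {
  if (!length(hi_impacts) || !length(lo_impacts)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  tp <- sum(hi_impacts >= cutoff)
  fn <- sum(hi_impacts < cutoff)
  tn <- sum(lo_impacts < cutoff)
  fp <- sum(lo_impacts >= cutoff)
  .kc_validity(
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    basis = "empirical"
  )
}

#' Model-based classification validity at a cutoff
#'
#' Uses the fitted normal models directly: sensitivity is the upper-tail
#' probability of the criterion group's normal beyond the cutoff, specificity
#' the lower-tail probability of the contrast group's normal, and accuracy
#' their n-weighted mean.
#'
#' @param hi,lo `group_stats` objects.
#' @param cutoff classification threshold (levels).
#' @return a `validity_indices` with `basis = "model"`.
#' @export
model_validity <- function(hi, lo, cutoff) {
  stopifnot(inherits(hi, "group_stats"), inherits(lo, "group_stats"))
  sens <- stats::pnorm(cutoff, hi$mean, hi$sd, lower.tail = FALSE)
  spec <- stats::pnorm(cutoff, lo$mean, lo$sd)
  .kc_validity(
    accuracy = (hi$n * sens + lo$n * spec) / (hi$n + lo$n),
    sensitivity = sens, specificity = spec,
    counts = NULL, basis = "model"
  )
}

#' Candidate integer levels around a continuous cutoff
#'
#' Returns the `2 * window + 1` consecutive integers centred at the half-up
#' rounding of the continuous cutoff, dropping any level below 1.
#'
#' @param continuous_cutoff the continuous reference point B.
#' @param window half-width of the candidate window (>= 1).
#' @return integer vector of candidate levels.
#' @export
candidate_levels <- function(continuous_cutoff, window = 1) {
  stopifnot(is.numeric(continuous_cutoff), length(continuous_cutoff) == 1,
            window >= 1, window == round(window))
  center <- as.integer(round_half_up(continuous_cutoff, 0))
  lev <- (center - as.integer(window)):(center + as.integer(window))
  lev[lev >= 1L]
}

#' Select an integer scoring level from validated candidates
#'
#' The decision rule: maximize classification accuracy; break exact accuracy
#' ties by the larger sensitivity; break any remaining tie by the lower level
#' (conservative toward easier scoring). `tie_broken` flags that the
#' top-accuracy set had more than one member, so a tie-break was exercised.
#'
#' @param candidates data.frame with columns `level`, `accuracy` and
#'   optionally `sensitivity` (missing sensitivities never win a tie).
#' @return list with `selected_level` (integer) and `tie_broken` (logical).
#' @export
select_level <- function(candidates) {
  if (is.list(candidates) && !is.data.frame(candidates)) {
    candidates <- do.call(rbind, lapply(candidates, as.data.frame))
  }
  stopifnot(is.data.frame(candidates))
  if (!nrow(candidates)) stop("no candidate levels", call. = FALSE)
  if (!all(c("level", "accuracy") %in% names(candidates))) {
    stop("candidates need columns 'level' and 'accuracy'", call. = FALSE)
  }
  if (anyDuplicated(candidates$level)) {
    stop("duplicate candidate levels", call. = FALSE)
  }
  sens <- if ("sensitivity" %in% names(candidates)) {
    ifelse(is.na(candidates$sensitivity), -Inf, candidates$sensitivity)
  } else {
    rep(-Inf, nrow(candidates))
  }
  top <- which(candidates$accuracy == max(candidates$accuracy))
  tie_broken <- length(top) > 1
  if (tie_broken) {
    top <- top[sens[top] == max(sens[top])]
    if (length(top) > 1) top <- top[which.min(candidates$level[top])]
  }
  list(selected_level = as.integer(candidates$level[top]),
       tie_broken = tie_broken)
}
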