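# Data model and I/O for per-kick impact records and certified threshold tables.
#
# A "kick event" is one registered trunk hit on the electronic body protector
# (PSS), carrying its competition stratum (gender, weight class), the kicker's
# match outcome role, whether the hit scored or was merely effective, and the
# registered impact level.

.kc_genders <- c("men", "women")

.kc_weight_classes <- list(
  men   = c("U58", "U63", "U68", "U80", "O80"),
  women = c("U49", "U53", "U57", "U67", "O67")
)

.kc_roles <- c("winner", "non_winner")
.kc_hit_types <- c("scoring", "effective")

.kc_event_columns <- c("match_id", "gender", "weight_class",
                       "athlete_role", "hit_type", "impact")

# Certified scoring thresholds (column "A"): the impact level at or above
# which a trunk hit auto-scores, per gender and weight class.
.kc_wt_defaults <- list(
  men   = c(U58 = 18L, U63 = 20L, U68 = 21L, U80 = 23L, O80 = 25L),
  women = c(U49 = 16L, U53 = 17L, U57 = 18L, U67 = 20L, O67 = 22L)
)

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1`), the convention used in
#' printed percentage tables, as opposed to base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalize a weight-class label
#'
#' Maps free-text class labels ("under 58 kg", "over 80 kg", "+ 80 kg",
#' "over 87 kg") onto the canonical U/O codes. Heavyweight variants
#' ("over 80", "+80", "over 87") all map to `O80` for men; already-canonical
#' codes pass through.
#'
#' @param x character vector of class labels.
#' @param gender `"men"` or `"women"`.
#' @return character vector of canonical codes.
#' @export
normalize_weight_class <- function(x, gender) {
  gender <- match.arg(gender, .kc_genders)
  valid <- .kc_weight_classes[[gender]]
  out <- toupper(trimws(x))
  raw <- tolower(trimws(x))
  for (i in seq_along(raw)) {
    if (out[i] %in% valid) next
    s <- gsub("[^a-z0-9+]", "", raw[i])
    num <- regmatches(s, regexpr("[0-9]+", s))
    if (grepl("^over|^\\+|^o", s) && length(num)) {
      code <- paste0("O", num)
      # the heavyweight stratum is labelled inconsistently in source tables
      if (gender == "men" && num %in% c("80", "87")) code <- "O80"
      out[i] <- code
    } else if (grepl("^under|^u", s) && length(num)) {
      out[i] <- paste0("U", num)
    }
  }
  bad <- !(out %in% valid)
  if (any(bad)) {
    stop(sprintf("invalid weight class(es) for %s: %s", gender,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

.kc_validate_events <- function(events, max_level) {
  problems <- character(0)
  add <- function(rows, what) {
    if (length(rows)) {
      sprintf("row %d: %s", rows, what)
    } else {
      character(0)
    }
  }
  n <- nrow(events)
  bad_gender <- which(!(events$gender %in% .kc_genders))
  problems <- c(problems, add(bad_gender, "gender must be 'men' or 'women'"))
  ok_gender <- setdiff(seq_len(n), bad_gender)
  if (length(ok_gender)) {
    valid_wc <- vapply(ok_gender, function(i) {
      events$weight_class[i] %in% .kc_weight_classes[[events$gender[i]]]
    }, logical(1))
    problems <- c(problems,
                  add(ok_gender[!valid_wc], "weight_class invalid for gender"))
  }
  problems <- c(problems,
                add(which(!(events$athlete_role %in% .kc_roles)),
                    "athlete_role must be 'winner' or 'non_winner'"),
                add(which(!(events$hit_type %in% .kc_hit_types)),
                    "hit_type must be 'scoring' or 'effective'"))
  imp <- events$impact
  problems <- c(problems,
                add(which(!is.finite(imp)), "impact is not a finite number"),
                add(which(is.finite(imp) & imp <= 0), "impact must be positive"),
                add(which(is.finite(imp) & imp > max_level),
                    sprintf("impact exceeds the maximum level %s", max_level)))
  problems
}

#' Construct a validated impact dataset
#'
#' @param events data.frame with columns `match_id`, `gender`, `weight_class`,
#'   `athlete_role`, `hit_type`, `impact` (one row per registered trunk hit).
#' @param provenance free-text source tag.
#' @param seed integer seed when the dataset is synthetic, else `NA`.
#' @param max_level maximum admissible impact level (default 60).
#' @return an `impact_dataset` object.
#' @export
impact_dataset <- function(events, provenance = "unspecified", seed = NA_integer_,
                           max_level = 60) {
  stopifnot(is.data.frame(events))
  missing_cols <- setdiff(.kc_event_columns, names(events))
  if (length(missing_cols)) {
    stop("events is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  events <- events[, .kc_event_columns, drop = FALSE]
  events$match_id <- as.character(events$match_id)
  events$gender <- as.character(events$gender)
  events$weight_class <- as.character(events$weight_class)
  events$athlete_role <- as.character(events$athlete_role)
  events$hit_type <- as.character(events$hit_type)
  events$impact <- as.numeric(events$impact)
  rownames(events) <- NULL
  problems <- .kc_validate_events(events, max_level)
  if (length(problems)) {
    stop("invalid kick events:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(
    list(events = events, provenance = provenance,
         seed = if (is.na(seed)) NA_integer_ else as.integer(seed),
         max_level = max_level),
    class = "impact_dataset"
  )
}

#' @export
print.impact_dataset <- function(x, ...) {
  cat(sprintf("<impact_dataset: %d events, provenance: %s>\n",
              nrow(x$events), x$provenance))
  if (nrow(x$events)) {
    tab <- table(x$events$gender, x$events$weight_class)
    print(tab)
  }
  invisible(x)
}

#' Number of events in a dataset
#' @param dataset an `impact_dataset`.
#' @return integer event count.
#' @export
n_events <- function(dataset) {
  stopifnot(inherits(dataset, "impact_dataset"))
  nrow(dataset$events)
}

#' Read kick events from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row naming the six
#' event fields. Malformed rows are reported by data-row number (header
#' excluded). Row order is preserved.
#'
#' @param path file path.
#' @param max_level maximum admissible impact level.
#' @return an `impact_dataset`.
#' @export
read_events <- function(path, max_level = 60) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.kc_event_columns, names(raw))
  if (length(missing_cols)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, .kc_event_columns, drop = FALSE]
  imp <- suppressWarnings(as.numeric(raw$impact))
  bad <- which(is.na(imp) & nzchar(raw$impact) | !nzchar(raw$impact))
  if (length(bad)) {
    stop(sprintf("validation error in %s: non-numeric impact at row(s) %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  raw$impact <- imp
  problems <- .kc_validate_events(raw, max_level)
  if (length(problems)) {
    stop(sprintf("validation error in %s:\n  %s", path,
                 paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  impact_dataset(raw, provenance = path, max_level = max_level)
}

#' Write kick events to CSV
#'
#' Impacts are serialized with 17 significant digits so that
#' `read_events(write_events(d))` reproduces every field exactly.
#'
#' @param dataset an `impact_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(dataset, path) {
  stopifnot(inherits(dataset, "impact_dataset"))
  out <- dataset$events
  out$impact <- sprintf("%.17g", out$impact)
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8"),
    error = function(e) stop("cannot write events to ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Load the certified threshold table
#'
#' With no path, returns the bundled federation-certified levels (column A).
#' A JSON config of the form `{"men": {"U58": 19}, ...}` overrides individual
#' strata; unlisted strata keep their defaults. The returned table always
#' covers all 10 gender-by-class strata.
#'
#' @param path optional JSON config path.
#' @return a `threshold_table` object.
#' @export
load_thresholds <- function(path = NULL) {
  entries <- .kc_wt_defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("threshold config not found: ", path, call. = FALSE)
    cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    bad_gender <- setdiff(names(cfg), .kc_genders)
    if (length(bad_gender)) {
      stop("unknown gender in threshold config: ",
           paste(bad_gender, collapse = ", "), call. = FALSE)
    }
    for (g in names(cfg)) {
      levels <- unlist(cfg[[g]])
      bad_wc <- setdiff(names(levels), .kc_weight_classes[[g]])
      if (length(bad_wc)) {
        stop("unknown weight class in threshold config for ", g, ": ",
             paste(bad_wc, collapse = ", "), call. = FALSE)
      }
      if (any(!is.finite(levels) | levels <= 0 | levels != round(levels))) {
        stop("threshold levels must be positive integers", call. = FALSE)
      }
      entries[[g]][names(levels)] <- as.integer(levels)
    }
  }
  missing <- unlist(lapply(.kc_genders, function(g) {
    m <- setdiff(.kc_weight_classes[[g]], names(entries[[g]]))
    if (length(m)) paste(g, m) else character(0)
  }))
  if (length(missing)) {
    stop("threshold table incomplete; missing strata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries), class = "threshold_table")
}

#' Look up the certified level A for one stratum
#'
#' @param thresholds a `threshold_table`.
#' @param gender `"men"` or `"women"`.
#' @param weight_class canonical class code.
#' @return integer level.
#' @export
wt_level <- function(thresholds, gender, weight_class) {
  stopifnot(inherits(thresholds, "threshold_table"))
  gender <- match.arg(gender, .kc_genders)
  weight_class <- match.arg(weight_class, .kc_weight_classes[[gender]])
  unname(thresholds$entries[[gender]][[weight_class]])
}

#' @export
print.threshold_table <- function(x, ...) {
  cat("<threshold_table (certified scoring levels A)>\n")
  for (g in names(x$entries)) {
    cat(" ", g, ": ",
        paste(sprintf("%s=%d", names(x$entries[[g]]), x$entries[[g]]),
              collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Match-composition share table
#'
#' Recomputes the per-class match counts and their percentage shares for one
#' gender, the way competition composition tables are printed: percent =
#' 100 * count / total, rounded half-up to one decimal.
#'
#' @param match_counts named non-negative integer vector (names are weight
#'   classes); at least one count must be positive.
#' @param gender `"men"` or `"women"`.
#' @return data.frame with columns `weight_class`, `count`, `percent`; the
#'   grand total is attached as attribute `"total"`.
#' @export
match_share_table <- function(match_counts, gender) {
  gender <- match.arg(gender, .kc_genders)
  if (is.null(names(match_counts)) || any(!nzchar(names(match_counts)))) {
    stop("match_counts must be a named vector", call. = FALSE)
  }
  classes <- normalize_weight_class(names(match_counts), gender)
  counts <- as.numeric(match_counts)
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts))) {
    stop("match counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("all match counts are zero", call. = FALSE)
  out <- data.frame(
    weight_class = classes,
    count = as.integer(counts),
    percent = round_half_up(100 * counts / total, 1),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- as.integer(total)
  out
}
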