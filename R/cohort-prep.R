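#' Horizon label of a scan
#'
#' Binary event-within-horizon label with an inclusive boundary: 1 when the
#' event occurs within `h` years of the scan (event at exactly `h` years
#' counts positive); 0 when follow-up (the event time itself, or the
#' censoring time for event-free subjects) extends at least `h` years beyond
#' the scan without an event; `NA` (undefined — the scan is excluded at this
#' horizon) when the subject is censored before `scan_time + h`.
#'
#' @param scan_time Scan time in years from baseline (vectorized).
#' @param event_time Event time in years, `NA` when censored.
#' @param censor_time Censoring time in years (last follow-up); ignored when
#'   the event is observed.
#' @param h Horizon in years (> 0).
#' @return Integer vector in {0, 1, NA}.
#' @export
label_for_horizon <- function(scan_time, event_time, censor_time, h) {
  stopifnot(h > 0)
  n <- length(scan_time)
  event_time <- rep_len(event_time, n)
  censor_time <- rep_len(censor_time, n)
  out <- rep(NA_integer_, n)
  has_ev <- !is.na(event_time)
  out[has_ev & event_time - scan_time <= h] <- 1L
  out[has_ev & event_time - scan_time > h] <- 0L
  out[!has_ev & censor_time - scan_time >= h] <- 0L
  out
}

SET_LEVELS <- c("set1", "set2", "set3", "single")

set_id_of <- function(y1, y2) {
  ifelse(is.na(y2), "single",
    ifelse(y1 == 0 & y2 == 1, "set1",
      ifelse(y1 == 0 & y2 == 0, "set2", "set3")))
}

#' Build training/evaluation scan pairs at a horizon
#'
#' For each subject, scan 1 is the baseline scan. The second scan is chosen
#' by the case/control rule: subjects with an observed event take their
#' latest scan acquired 1-4 years (inclusive) before the event; event-free
#' subjects take their latest follow-up scan that still has at least `h`
#' years of follow-up beyond it (so its label is defined). Subjects with no
#' eligible second scan contribute a single-scan unit. Each pair carries its
#' horizon labels and a group id: `set1` (progression, 0 to 1), `set2`
#' (stable negative), `set3` (stable positive), or `single`.
#'
#' Subjects without a baseline scan, or whose baseline label is undefined at
#' this horizon, are skipped with a warning.
#'
#' @param manifest Cohort manifest data.frame (see [simulate_cohort()]).
#' @param h Horizon in years.
#' @param case_window Inclusive (min, max) years between the second scan and
#'   the event for case second-scan eligibility.
#' @return A data.frame with one row per subject: `subject_id`, `scan1_time`,
#'   `scan2_time` (NA for singles), `payload1`, `payload2`, `grade1`,
#'   `grade2`, `y1`, `y2`, `set_id`, `horizon`.
#' @export
select_training_scans <- function(manifest, h, case_window = c(1, 4)) {
  stopifnot(h > 0, length(case_window) == 2L, case_window[1] <= case_window[2])
  subs <- split(manifest, manifest$subject_id)
  skipped <- character()
  rows <- lapply(subs, function(sc) {
    sc <- sc[order(sc$scan_time_years), , drop = FALSE]
    if (sc$scan_time_years[1] != 0) {
      skipped <<- c(skipped, sc$subject_id[1]); return(NULL)
    }
    ev <- sc$event_time_years[1]
    cens <- max(sc$scan_time_years)
    y <- label_for_horizon(sc$scan_time_years, ev, cens, h)
    if (is.na(y[1])) { skipped <<- c(skipped, sc$subject_id[1]); return(NULL) }
    later <- sc$scan_time_years > 0
    if (!is.na(ev)) {
      gap <- ev - sc$scan_time_years
      elig <- later & gap >= case_window[1] & gap <= case_window[2]
    } else {
      elig <- later & !is.na(y)
    }
    i2 <- if (any(elig)) max(which(elig)) else NA_integer_
    data.frame(
      subject_id = sc$subject_id[1],
      scan1_time = sc$scan_time_years[1],
      scan2_time = if (is.na(i2)) NA_real_ else sc$scan_time_years[i2],
      payload1 = sc$payload_ref[1],
      payload2 = if (is.na(i2)) NA_character_ else sc$payload_ref[i2],
      grade1 = sc$grade[1],
      grade2 = if (is.na(i2)) NA_integer_ else sc$grade[i2],
      y1 = y[1],
      y2 = if (is.na(i2)) NA_integer_ else y[i2],
      stringsAsFactors = FALSE)
  })
  if (length(skipped) > 0) {
    warning(sprintf("skipped %d subject(s) without a usable baseline at horizon %g: %s",
                    length(skipped), h,
                    paste(utils::head(skipped, 5), collapse = ", ")),
            call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(subject_id = character(), scan1_time = numeric(),
                      scan2_time = numeric(), payload1 = character(),
                      payload2 = character(), grade1 = integer(),
                      grade2 = integer(), y1 = integer(), y2 = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out$set_id <- set_id_of(out$y1, out$y2)
  out$horizon <- rep(h, nrow(out))
  out
}

#' Match cases to controls on demographics
#'
#' One-to-one case-control matching under the constraints: identical integer
#' age (widenable to +/- `age_tolerance` years for sparse cohorts),
#' identical sex, identical ethnicity, and baseline BMI within a relative
#' tolerance anchored on the case's BMI
#' (`|bmi_case - bmi_control| <= bmi_tolerance * bmi_case`). The pairing is
#' solved as maximum-cardinality bipartite matching, so the result does not
#' depend on subject order and never strands a matchable case the way a
#' greedy pass can.
#'
#' @param subjects Data.frame with one row per subject: `subject_id`, `age`,
#'   `sex`, `ethnicity`, `bmi`, and `is_case` (logical). Use
#'   [cohort_subjects()] to derive it from a manifest.
#' @param bmi_tolerance Relative BMI tolerance (default 0.10).
#' @param age_tolerance Allowed absolute age difference in years (default 0,
#'   i.e. same age).
#' @return Data.frame of matched pairs (`case_id`, `control_id`) with the
#'   unmatched subject ids in `attr(, "unmatched")`.
#' @export
match_case_control <- function(subjects, bmi_tolerance = 0.10,
                               age_tolerance = 0) {
  stopifnot(all(c("subject_id", "age", "sex", "ethnicity", "bmi", "is_case")
                %in% names(subjects)))
  cases <- subjects[subjects$is_case, , drop = FALSE]
  ctrls <- subjects[!subjects$is_case, , drop = FALSE]
  empty <- data.frame(case_id = character(), control_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cases) == 0L || nrow(ctrls) == 0L) {
    attr(empty, "unmatched") <- subjects$subject_id
    return(empty)
  }
  # candidate edges satisfying all four constraints
  edges <- NULL
  for (i in seq_len(nrow(cases))) {
    ok <- abs(ctrls$age - cases$age[i]) <= age_tolerance &
      ctrls$sex == cases$sex[i] &
      ctrls$ethnicity == cases$ethnicity[i] &
      abs(ctrls$bmi - cases$bmi[i]) <= bmi_tolerance * cases$bmi[i]
    if (any(ok)) edges <- rbind(edges, cbind(i, which(ok)))
  }
  if (is.null(edges)) {
    attr(empty, "unmatched") <- subjects$subject_id
    return(empty)
  }
  nc <- nrow(cases)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nc), rep(TRUE, nrow(ctrls))),
    edges = as.vector(t(cbind(edges[, 1], edges[, 2] + nc))))
  mm <- igraph::max_bipartite_match(g)$matching
  matched_case <- which(!is.na(mm[seq_len(nc)]))
  out <- data.frame(case_id = cases$subject_id[matched_case],
                    control_id = ctrls$subject_id[mm[matched_case] - nc],
                    stringsAsFactors = FALSE)
  attr(out, "unmatched") <- setdiff(subjects$subject_id,
                                    c(out$case_id, out$control_id))
  out
}

#' One row per subject from a scan-level manifest
#'
#' @param manifest Cohort manifest data.frame.
#' @return Data.frame with `subject_id`, demographics, `event_time_years`,
#'   `censor_time` (last scan time) and `is_case`.
#' @export
cohort_subjects <- function(manifest) {
  subs <- split(manifest, manifest$subject_id)
  out <- do.call(rbind, lapply(subs, function(sc) {
    data.frame(subject_id = sc$subject_id[1], age = sc$age[1],
               sex = sc$sex[1], ethnicity = sc$ethnicity[1], bmi = sc$bmi[1],
               event_time_years = sc$event_time_years[1],
               censor_time = max(sc$scan_time_years),
               is_case = !is.na(sc$event_time_years[1]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Nested cross-validation split plan
#'
#' Assigns each subject to one of `outer` folds, stratified by case/control
#' status, at the subject level. The inner cross-validation reuses the
#' remaining folds: for each outer test fold, each of the other `outer - 1`
#' folds serves once as the validation fold, the rest as training — giving
#' `outer * (outer - 1)` (train, validation, test) assignments (42 with the
#' default 7 x 6) with approximate fractions 5/7, 1/7, 1/7. Deterministic
#' given `seed`.
#'
#' @param subject_ids Character vector of subject ids.
#' @param is_case Logical stratum flag, same length.
#' @param outer Number of outer folds (default 7).
#' @param inner Number of inner folds; must equal `outer - 1` (default 6).
#' @param seed Integer seed.
#' @return An object of class `split_plan`: data.frame (`subject_id`,
#'   `fold`) with attributes `outer`, `inner`, `seed`.
#' @export
make_nested_splits <- function(subject_ids, is_case, outer = 7, inner = 6,
                               seed = 1L) {
  stopifnot(length(subject_ids) == length(is_case),
            !anyDuplicated(subject_ids))
  if (inner != outer - 1) {
    stop("`inner` must equal `outer - 1`: inner folds reuse the non-test outer folds",
         call. = FALSE)
  }
  tab <- table(is_case)
  if (length(tab) < 2L || any(tab < outer)) {
    stop(sprintf("need at least %d subjects in each stratum", outer),
         call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(subject_ids))
  for (stratum in unique(is_case)) {
    idx <- which(is_case == stratum)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(outer) - 1L, length(idx))
  }
  structure(data.frame(subject_id = subject_ids, fold = fold,
                       stringsAsFactors = FALSE),
            outer = as.integer(outer), inner = as.integer(inner),
            seed = as.integer(seed), class = c("split_plan", "data.frame"))
}

#' Enumerate the (train, validation, test) assignments of a split plan
#'
#' @param plan A [make_nested_splits()] result.
#' @return Data.frame with one row per assignment: `outer_fold` (the test
#'   fold), `inner_index` (0-based position of the validation fold among the
#'   non-test folds) and `val_fold`.
#' @export
split_assignments <- function(plan) {
  outer <- attr(plan, "outer")
  out <- do.call(rbind, lapply(seq_len(outer) - 1L, function(o) {
    vals <- setdiff(seq_len(outer) - 1L, o)
    data.frame(outer_fold = o, inner_index = seq_along(vals) - 1L,
               val_fold = vals)
  }))
  rownames(out) <- NULL
  out
}

#' Subject ids in the train/validation/test roles of one assignment
#'
#' @param plan A [make_nested_splits()] result.
#' @param outer_fold Test fold index.
#' @param val_fold Validation fold index (must differ from `outer_fold`).
#' @return List with character vectors `train`, `val`, `test`.
#' @export
split_members <- function(plan, outer_fold, val_fold) {
  stopifnot(outer_fold != val_fold)
  list(train = plan$subject_id[!plan$fold %in% c(outer_fold, val_fold)],
       val = plan$subject_id[plan$fold == val_fold],
       test = plan$subject_id[plan$fold == outer_fold])
}
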