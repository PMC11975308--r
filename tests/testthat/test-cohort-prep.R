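manifest_row <- function(id, t, ev = NA_real_, grade = 1L, age = 60,
                         sex = "F", eth = "A", bmi = 28) {
  data.frame(subject_id = id, scan_time_years = t,
             payload_ref = sprintf("%s_t%g", id, t), grade = grade,
             age = age, sex = sex, ethnicity = eth, bmi = bmi,
             event_time_years = ev, stringsAsFactors = FALSE)
}

test_that("horizon labels follow the inclusive-boundary rule", {
  # event 2.5 years after the scan
  expect_equal(label_for_horizon(0, 2.5, NA, 2), 0L)
  expect_equal(label_for_horizon(0, 2.5, NA, 4), 1L)
  # event exactly at the horizon counts positive
  expect_equal(label_for_horizon(0, 2, NA, 2), 1L)
  # censored 1 year after the scan: undefined at h = 4
  expect_true(is.na(label_for_horizon(0, NA, 1, 4)))
  # follow-up exactly h years counts as a defined negative
  expect_equal(label_for_horizon(0, NA, 4, 4), 0L)
})

test_that("case second scans are the latest within the pre-event window", {
  # scans at 0..3, event at 3.5: gaps 3.5, 2.5, 1.5, 0.5 -> latest in [1,4] is t=2
  m <- do.call(rbind, lapply(0:3, function(t) manifest_row("C1", t, ev = 3.5)))
  p <- select_training_scans(m, h = 2)
  expect_equal(p$scan2_time, 2)
  expect_equal(p$y1, 0L)          # event 3.5 > 2
  expect_equal(p$y2, 1L)          # 1.5 <= 2
  expect_equal(p$set_id, "set1")
  # exhaustive check of the eligibility rule over all scans
  gaps <- 3.5 - (0:3)
  elig <- (0:3) > 0 & gaps >= 1 & gaps <= 4
  expect_equal(p$scan2_time, max((0:3)[elig]))
})

test_that("subjects without an eligible second scan become singles", {
  # control with only the baseline scan
  m <- manifest_row("X1", 0)
  expect_warning(p <- select_training_scans(m, h = 2), "skipped")
  expect_equal(nrow(p), 0)  # censored at 0: baseline label undefined
  # control followed long enough: single with y1 = 0
  m2 <- rbind(manifest_row("X2", 0), manifest_row("X2", 1))
  p2 <- select_training_scans(m2, h = 1)
  expect_equal(p2$set_id, "single")
  expect_equal(p2$y1, 0L)
  # early-event case with only a baseline: single positive at h >= 1
  m3 <- manifest_row("X3", 0, ev = 0.5)
  p3 <- select_training_scans(m3, h = 1)
  expect_equal(p3$set_id, "single")
  expect_equal(p3$y1, 1L)
  expect_true(is.na(p3$scan2_time))
})

test_that("controls take the latest follow-up scan with a defined label", {
  m <- do.call(rbind, lapply(0:6, function(t) manifest_row("K1", t)))
  p <- select_training_scans(m, h = 2)
  # censored at 6: the latest scan with >= 2 years beyond it is t = 4
  expect_equal(p$scan2_time, 4)
  expect_equal(p$set_id, "set2")
  p4 <- select_training_scans(m, h = 4)
  expect_equal(p4$scan2_time, 2)
})

test_that("pair labels never regress and set3 is empty at horizon 1", {
  co <- small_cohort(n = 200, seed = 17)
  for (h in c(1, 2, 4)) {
    p <- suppressWarnings(select_training_scans(co$manifest, h))
    expect_equal(sum(p$y1 == 1 & p$y2 == 0, na.rm = TRUE), 0)
    # set_id is consistent with the labels
    with2 <- p[!is.na(p$y2), ]
    expect_equal(with2$set_id,
                 ifelse(with2$y1 == 0 & with2$y2 == 1, "set1",
                        ifelse(with2$y2 == 0, "set2", "set3")))
  }
  p1 <- suppressWarnings(select_training_scans(co$manifest, 1))
  expect_equal(sum(p1$set_id == "set3"), 0)
})

subject_row <- function(id, is_case, age = 60, sex = "F", eth = "A",
                        bmi = 30) {
  data.frame(subject_id = id, age = age, sex = sex, ethnicity = eth,
             bmi = bmi, is_case = is_case, stringsAsFactors = FALSE)
}

test_that("matching enforces all four constraints", {
  subj <- rbind(subject_row("case1", TRUE, bmi = 30),
                subject_row("ctl1", FALSE, bmi = 32.9),
                subject_row("ctl2", FALSE, bmi = 34))   # > 10% of 30
  mm <- match_case_control(subj)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$control_id, "ctl1")
  # no controls at all
  expect_equal(nrow(match_case_control(subj[1, ])), 0)
  # sex/ethnicity/age must be identical
  subj2 <- rbind(subject_row("c", TRUE),
                 subject_row("k1", FALSE, sex = "M"),
                 subject_row("k2", FALSE, eth = "B"),
                 subject_row("k3", FALSE, age = 61))
  expect_equal(nrow(match_case_control(subj2)), 0)
  expect_equal(nrow(match_case_control(subj2, age_tolerance = 1)), 1)
})

test_that("matching is maximum-cardinality, not greedy", {
  # case A matches both controls, case B only control 1: a greedy pass that
  # gives control 1 to case A strands case B
  subj <- rbind(subject_row("A", TRUE, bmi = 30),
                subject_row("B", TRUE, bmi = 27.5),
                subject_row("u1", FALSE, bmi = 28),   # ok for A and B
                subject_row("u2", FALSE, bmi = 32))   # ok for A only
  mm <- match_case_control(subj)
  expect_equal(nrow(mm), 2)
  expect_setequal(mm$case_id, c("A", "B"))
  expect_equal(mm$control_id[mm$case_id == "B"], "u1")
})

test_that("matching cardinality equals the brute-force optimum on toy cohorts", {
  set.seed(41)
  for (rep in 1:20) {
    n_case <- sample(2:4, 1)
    n_ctl <- sample(2:4, 1)
    subj <- rbind(
      do.call(rbind, lapply(seq_len(n_case), function(i) {
        subject_row(paste0("c", i), TRUE, age = sample(60:61, 1),
                    bmi = runif(1, 25, 32))
      })),
      do.call(rbind, lapply(seq_len(n_ctl), function(i) {
        subject_row(paste0("k", i), FALSE, age = sample(60:61, 1),
                    bmi = runif(1, 25, 32))
      })))
    mm <- match_case_control(subj)
    cases <- subj[subj$is_case, ]
    ctls <- subj[!subj$is_case, ]
    adj <- outer(seq_len(n_case), seq_len(n_ctl), Vectorize(function(i, j) {
      cases$age[i] == ctls$age[j] && cases$sex[i] == ctls$sex[j] &&
        cases$ethnicity[i] == ctls$ethnicity[j] &&
        abs(cases$bmi[i] - ctls$bmi[j]) <= 0.1 * cases$bmi[i]
    }))
    expect_equal(nrow(mm), brute_max_matching(adj))
  }
})

test_that("matched pairs re-verify against all constraints on a simulated cohort", {
  co <- small_cohort(n = 250, seed = 19)
  subj <- cohort_subjects(co$manifest)
  mm <- match_case_control(subj)
  expect_gt(nrow(mm), 0)
  ca <- subj[match(mm$case_id, subj$subject_id), ]
  ct <- subj[match(mm$control_id, subj$subject_id), ]
  expect_equal(sum(ca$age != ct$age), 0)
  expect_equal(sum(ca$sex != ct$sex), 0)
  expect_equal(sum(ca$ethnicity != ct$ethnicity), 0)
  expect_equal(sum(abs(ca$bmi - ct$bmi) > 0.10 * ca$bmi), 0)
  # one-to-one usage
  expect_false(any(duplicated(c(mm$case_id, mm$control_id))))
})

test_that("nested splits partition subjects and enumerate 42 assignments", {
  ids <- sprintf("S%02d", 1:42)
  is_case <- rep(c(TRUE, FALSE), each = 21)
  plan <- make_nested_splits(ids, is_case, seed = 4)
  # exact divisibility: 6 subjects per fold, 3 per stratum
  expect_equal(as.integer(table(plan$fold)), rep(6L, 7))
  tab <- table(plan$fold, is_case)
  expect_true(all(tab == 3))
  asn <- split_assignments(plan)
  expect_equal(nrow(asn), 42)
  for (k in seq_len(nrow(asn))) {
    mem <- split_members(plan, asn$outer_fold[k], asn$val_fold[k])
    expect_length(intersect(mem$train, mem$val), 0)
    expect_length(intersect(mem$train, mem$test), 0)
    expect_length(intersect(mem$val, mem$test), 0)
    expect_setequal(c(mem$train, mem$val, mem$test), ids)
  }
  # determinism
  expect_identical(plan, make_nested_splits(ids, is_case, seed = 4))
  expect_false(identical(plan$fold,
                         make_nested_splits(ids, is_case, seed = 5)$fold))
  expect_error(make_nested_splits(ids[1:10], is_case[1:10] & FALSE),
               "stratum")
})
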