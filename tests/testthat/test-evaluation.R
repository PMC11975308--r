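test_that("auroc matches the pairwise probability form", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auroc(c(0, 1), c(0.1, 0.9)), 1.0)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)  # all ties
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "one class")
  expect_error(auroc(c(0, 1), c(0.2)), "equal length")
})

test_that("auprc follows the step-wise average-precision rule", {
  expect_equal(auprc(c(0, 1), c(0.2, 0.8)), 1.0)
  # positive found at rank 2 of 2
  expect_equal(auprc(c(1, 0), c(0.2, 0.8)), 0.5)
  expect_error(auprc(c(0, 0), c(0.2, 0.8)), "no positives")
  # random scores approximate the prevalence
  set.seed(31)
  lab <- rbinom(20000, 1, 0.15)
  expect_lt(abs(auprc(lab, runif(20000)) - mean(lab)), 0.02)
})

test_that("rank metrics agree with brute-force enumeration on small inputs", {
  set.seed(32)
  for (rep in 1:300) {
    n <- sample(2:12, 1)
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) next
    sc <- round(runif(n), sample(c(1, 2, 6), 1))  # include heavy ties
    expect_equal(auroc(lab, sc), brute_auroc(lab, sc), tolerance = 1e-12)
    expect_equal(auprc(lab, sc), brute_auprc(lab, sc), tolerance = 1e-12)
  }
})

test_that("auroc is invariant under strictly increasing transforms", {
  set.seed(33)
  lab <- rbinom(40, 1, 0.4)
  lab[1:2] <- c(0, 1)
  sc <- rnorm(40)
  expect_equal(auroc(lab, sc), auroc(lab, exp(sc)))
  expect_equal(auroc(lab, sc), auroc(lab, qlogis(plogis(sc))))
  d <- delong_pvalue(lab, sc, rnorm(40))
  d2 <- delong_pvalue(lab, exp(sc / 3), rnorm(40))  # same a-ranking
  expect_equal(d$auc_a, d2$auc_a)
})

test_that("auroc agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(34)
  lab <- rbinom(60, 1, 0.5); lab[1:2] <- c(0, 1)
  sc <- rnorm(60)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(lab, sc), ref, tolerance = 1e-12)
})

test_that("the DeLong test reproduces the structural-components oracle", {
  lab <- c(0, 0, 1, 1)
  a <- c(0.1, 0.4, 0.35, 0.8)
  b <- c(0.2, 0.3, 0.6, 0.7)
  d <- delong_pvalue(lab, a, b)
  # hand computation: V10_a = (.5, 1), V01_a = (1, .5), V10_b = V01_b = 1;
  # var = 0.125/2 + 0.125/2, z = -0.25 / sqrt(0.125)
  expect_equal(d$var_diff, 0.125, tolerance = 1e-12)
  expect_equal(d$z, -0.25 / sqrt(0.125), tolerance = 1e-12)
  expect_equal(d$p_value, 2 * pnorm(-abs(-0.25 / sqrt(0.125))),
               tolerance = 1e-12)
  # identical predictors: p = 1 by convention
  expect_equal(delong_pvalue(lab, a, a)$p_value, 1)
  expect_error(delong_pvalue(lab, a, b[1:3]), "paired")
})

test_that("the DeLong test agrees with pROC on larger paired data", {
  skip_if_not_installed("pROC")
  set.seed(35)
  n <- 150
  lab <- rbinom(n, 1, 0.5); lab[1:2] <- c(0, 1)
  x <- rnorm(n) + lab
  a <- x + rnorm(n, 0, 0.5)
  b <- x + rnorm(n, 0, 0.8)
  d <- delong_pvalue(lab, a, b)
  ref <- pROC::roc.test(pROC::roc(lab, a, quiet = TRUE, direction = "<"),
                        pROC::roc(lab, b, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(d$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
})

test_that("an informative predictor beats noise decisively at scale", {
  set.seed(36)
  n <- 2000
  lab <- rbinom(n, 1, 0.5)
  a <- lab + rnorm(n, 0, 0.7)
  b <- rnorm(n)
  expect_lt(delong_pvalue(lab, a, b)$p_value, 1e-6)
})

test_that("bootstrap intervals are deterministic and cover the point", {
  set.seed(37)
  lab <- rbinom(120, 1, 0.4); lab[1:2] <- c(0, 1)
  sc <- lab + rnorm(120)
  ci1 <- bootstrap_ci(auroc, lab, sc, n_boot = 200, seed = 9)
  ci2 <- bootstrap_ci(auroc, lab, sc, n_boot = 200, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], auroc(lab, sc))
  expect_gte(ci1[2], auroc(lab, sc))
  # zero-variance metric: degenerate interval at the point
  const <- function(labels, scores) 0.42
  ci0 <- bootstrap_ci(const, lab, sc, n_boot = 100, seed = 1)
  expect_equal(as.numeric(ci0), c(0.42, 0.42))
})

test_that("subgroup cohorts satisfy the inclusion algebra", {
  pred <- data.frame(
    subject_id = sprintf("S%02d", 1:8), scan_index = 1L,
    risk = runif(8), label = c(0, 0, 0, 0, 1, 1, 0, 0),
    grade = 1L,
    set_id = c("set1", "set1", "set2", "set2", "set3", "set3",
               "single", "single"),
    stringsAsFactors = FALSE)
  g <- build_subgroups(pred)
  expect_true(all(g$C1[g$C1] %in% g$C2[g$C1]))  # C1 subset of C2
  expect_true(all(which(g$C1) %in% which(g$C2)))
  expect_true(all(which(g$C1) %in% which(g$C3)))
  expect_false(any(g$C4 & pred$set_id == "set1"))
  # singles excluded everywhere
  expect_false(any((g$C1 | g$C2 | g$C3 | g$C4) & pred$set_id == "single"))
  # all pairs set2: C1 and C3 empty, C2 = C4 = everything
  pred2 <- pred; pred2$set_id <- "set2"
  g2 <- build_subgroups(pred2)
  expect_equal(sum(g2$C1), 0)
  expect_equal(sum(g2$C3), 0)
  expect_equal(g2$C2, g2$C4)
  # a lone set1 pair appears in C1, C2, C3 and not C4
  i <- pred$set_id == "set1"
  expect_true(all(g$C1[i] & g$C2[i] & g$C3[i] & !g$C4[i]))
})

test_that("per-grade AUROC is undefined (never 0 or 0.5) without both classes", {
  lab <- c(0, 1, 0, 1, 0, 0)
  sc <- c(0.2, 0.8, 0.3, 0.6, 0.1, 0.4)
  gr <- c(1, 1, 2, 2, 3, 3)
  out <- per_grade_auroc(lab, sc, gr)
  expect_equal(unname(out[c("grade1", "grade2")]), c(1, 1))
  expect_true(is.na(out["grade3"]))   # only negatives
  expect_true(is.na(out["grade0"]))   # no scans
})

test_that("eval_report assembles metrics, subgroups and contrasts", {
  set.seed(38)
  n <- 60
  base <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:(n / 2)), 2),
    scan_index = rep(1:2, each = n / 2),
    label = rep(c(rep(0L, n / 2), rbinom(n / 2, 1, 0.6))),
    grade = sample(0:4, n, replace = TRUE),
    set_id = "set1", stringsAsFactors = FALSE)
  pred <- rbind(transform(base, formulation = "baseline",
                          risk = plogis(label + rnorm(n))),
                transform(base, formulation = "riskform2",
                          risk = plogis(2 * label + rnorm(n))))
  rep_ <- eval_report(pred, n_boot = 100, seed = 2)
  expect_named(rep_$models, c("baseline", "riskform2"))
  m <- rep_$models$riskform2
  expect_true(m$auroc_ci[1] <= m$auroc && m$auroc <= m$auroc_ci[2])
  expect_equal(m$n, n)
  expect_true("baseline_vs_riskform2" %in% names(rep_$delong))
  expect_gte(rep_$delong$baseline_vs_riskform2$p_value, 0)
  # writes valid JSON and CSV
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep_, jp, cp)
  expect_true(jsonlite::validate(paste(readLines(jp), collapse = "")))
  tab <- read.csv(cp, stringsAsFactors = FALSE)
  expect_true(all(c("formulation", "cohort", "auroc_ci") %in% names(tab)))
})
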