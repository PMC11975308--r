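#' Simulation configuration for the synthetic longitudinal cohort
#'
#' The simulator emulates the statistical structure a progressive-disease
#' imaging cohort hands to the modelling code: each subject carries a latent
#' severity that starts at `s0` and increases linearly at a subject-specific
#' `rate` (zero for stable subjects), the terminal event fires when severity
#' crosses the threshold `theta`, scans are acquired at annual visits with
#' per-visit dropout, an ordinal grade 0-4 is read off the severity at scan
#' time, and demographics (integer age, binary sex, 3-level ethnicity,
#' log-normal BMI) are drawn so that exact case-control matching is feasible
#' but not trivial.
#'
#' @param n_subjects Number of subjects (one knee per subject).
#' @param prog_fraction Fraction of subjects with a positive progression rate;
#'   the rest have rate 0 and can never reach the event.
#' @param s0_range Range of the uniform baseline severity.
#' @param rate_shape,rate_rate Gamma parameters of the progressor slope
#'   (severity units per year).
#' @param theta Event threshold on the severity scale.
#' @param grade_cuts Four increasing severity cut points binning severity into
#'   grades 0-4 (left-closed bins: a severity exactly at a cut takes the
#'   higher grade).
#' @param n_visits Number of scheduled annual visits including baseline
#'   (visits at 0, 1, ..., n_visits - 1 years).
#' @param dropout Per-visit probability that a subject leaves the imaging
#'   schedule after the current visit (events are still ascertained through
#'   the study end, as with surgery registries).
#' @param payload `"feature"` for noisy feature-vector payloads or `"image"`
#'   for synthetic two-band grayscale scans.
#' @param feature_dim Dimension of the feature payload.
#' @param noise_sd Observation noise standard deviation added to feature
#'   payloads (per coordinate).
#' @param image_size Side length in pixels of image payloads.
#' @param image_noise_sd Pixelwise Gaussian noise sd of image payloads (on the
#'   0-1 intensity scale).
#' @param horizons Prediction horizons in years.
#' @param age_range Integer age range (years) sampled uniformly.
#' @param ethnicity_probs Probabilities of the three ethnicity categories.
#' @param bmi_meanlog,bmi_sdlog Log-normal BMI parameters (kg/m^2).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 500,
                       prog_fraction = 0.45,
                       s0_range = c(0, 2.5),
                       rate_shape = 4, rate_rate = 8,
                       theta = 4,
                       grade_cuts = c(0.8, 1.6, 2.4, 3.2),
                       n_visits = 10,
                       dropout = 0.05,
                       payload = c("feature", "image"),
                       feature_dim = 8,
                       noise_sd = 0.5,
                       image_size = 32,
                       image_noise_sd = 0.05,
                       horizons = c(1, 2, 4),
                       age_range = c(55, 70),
                       ethnicity_probs = c(0.6, 0.25, 0.15),
                       bmi_meanlog = log(28), bmi_sdlog = 0.12,
                       seed = 1L) {
  payload <- match.arg(payload)
  stopifnot(n_subjects >= 0, prog_fraction >= 0, prog_fraction <= 1,
            length(s0_range) == 2L, s0_range[1] >= 0, diff(s0_range) >= 0,
            rate_shape > 0, rate_rate > 0, theta > 0,
            length(grade_cuts) == 4L, all(diff(grade_cuts) > 0),
            n_visits >= 1, dropout >= 0, dropout < 1,
            feature_dim >= 1, noise_sd >= 0, image_size >= 8,
            image_noise_sd >= 0, all(horizons > 0),
            length(age_range) == 2L, diff(age_range) >= 0,
            length(ethnicity_probs) == 3L, abs(sum(ethnicity_probs) - 1) < 1e-8,
            bmi_sdlog >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects), prog_fraction = prog_fraction,
         s0_range = s0_range, rate_shape = rate_shape, rate_rate = rate_rate,
         theta = theta, grade_cuts = grade_cuts,
         n_visits = as.integer(n_visits), dropout = dropout,
         payload = payload, feature_dim = as.integer(feature_dim),
         noise_sd = noise_sd, image_size = as.integer(image_size),
         image_noise_sd = image_noise_sd, horizons = horizons,
         age_range = as.integer(age_range), ethnicity_probs = ethnicity_probs,
         bmi_meanlog = bmi_meanlog, bmi_sdlog = bmi_sdlog,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d subjects, %s payload, %d annual visits, seed %d\n",
    x$n_subjects, x$payload, x$n_visits, x$seed))
  invisible(x)
}

#' Latent severity of a trajectory at a time point
#'
#' Severity follows `s0 + rate * t`: linear, non-decreasing (rate >= 0), the
#' simplest dynamics consistent with a progressive disease whose event risk
#' never declines.
#'
#' @param traj A list (or one-row data.frame) with numeric `s0 >= 0` and
#'   `rate >= 0`.
#' @param t Time in years from baseline, `t >= 0` (vectorized).
#' @return Numeric severity values.
#' @export
severity_at <- function(traj, t) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  stopifnot(traj$rate >= 0, traj$s0 >= 0)
  traj$s0 + traj$rate * t
}

#' Latent event time of a trajectory
#'
#' The smallest `t >= 0` at which severity reaches the threshold `theta`:
#' `(theta - s0) / rate` when `s0 < theta` and `rate > 0`; `0` when the
#' subject starts at or beyond the threshold; `NA` (never crosses, censored)
#' for a stable subject (`rate = 0`) below the threshold.
#'
#' @param traj A list with numeric `s0`, `rate` and threshold `theta`.
#' @return Event time in years, or `NA_real_` when the event never occurs.
#' @export
event_time <- function(traj) {
  stopifnot(traj$theta > 0, traj$rate >= 0, traj$s0 >= 0)
  if (traj$s0 >= traj$theta) return(0)
  if (traj$rate == 0) return(NA_real_)
  (traj$theta - traj$s0) / traj$rate
}

#' Ordinal severity grade (0-4)
#'
#' Bins severity by the four cut points of the configuration into grades
#' 0..4 using left-closed/right-open bins, so a severity exactly at a cut
#' takes the higher grade. The grade is non-decreasing in severity, hence
#' non-decreasing over time within a subject.
#'
#' @param severity Numeric severity values (>= 0).
#' @param config A [sim_config()].
#' @return Integer grades in 0..4.
#' @export
grade_of <- function(severity, config = sim_config()) {
  if (any(severity < 0)) stop("`severity` must be non-negative", call. = FALSE)
  findInterval(severity, config$grade_cuts)
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 104729) %%
               2147483647)
}

#' Render a synthetic scan payload for a given severity
#'
#' Feature mode: returns `w * severity + eps` with `w` the fixed unit
#' direction `rep(1, d) / sqrt(d)` and `eps ~ N(0, noise_sd^2)` per
#' coordinate. Image mode: a grayscale square with two bright horizontal
#' bands whose vertical gap (a joint-space analog) shrinks linearly with
#' severity — gap(s) = gap(0) * max(0, 1 - s / theta) — plus pixelwise
#' Gaussian noise. Deterministic given `seed`.
#'
#' @param severity Non-negative severity.
#' @param cfg A [sim_config()].
#' @param seed Integer seed for the payload noise.
#' @return Feature mode: numeric vector of length `feature_dim`. Image mode:
#'   an `image_size` x `image_size` matrix with intensities in \[0, 1\].
#' @export
render_scan <- function(severity, cfg = sim_config(), seed = cfg$seed) {
  if (severity < 0) stop("`severity` must be non-negative", call. = FALSE)
  set.seed(seed)
  if (cfg$payload == "feature") {
    w <- rep(1, cfg$feature_dim) / sqrt(cfg$feature_dim)
    return(w * severity + stats::rnorm(cfg$feature_dim, 0, cfg$noise_sd))
  }
  n <- cfg$image_size
  img <- matrix(0.1, n, n)
  band_h <- max(1L, n %/% 8L)
  gap0 <- n %/% 2L
  gap <- as.integer(round(gap0 * max(0, 1 - severity / cfg$theta)))
  mid <- n %/% 2L
  top_lo <- max(1L, mid - gap %/% 2L - band_h + 1L)
  top_hi <- max(1L, mid - gap %/% 2L)
  bot_lo <- min(n, mid + (gap + 1L) %/% 2L + 1L)
  bot_hi <- min(n, bot_lo + band_h - 1L)
  img[top_lo:top_hi, ] <- 0.85
  img[bot_lo:bot_hi, ] <- 0.85
  if (cfg$image_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(n * n, 0, cfg$image_noise_sd), n, n)
  }
  pmin(pmax(img, 0), 1)
}

#' Vertical band gap of a rendered image, in pixels
#'
#' Measures the number of consecutive non-bright rows between the two bands
#' of a noiseless rendered scan; used to verify the severity-to-appearance
#' contract.
#' @param img Image matrix from [render_scan()].
#' @return Integer gap in rows.
#' @export
image_band_gap <- function(img) {
  bright <- rowMeans(img) > 0.5
  idx <- which(bright)
  if (length(idx) == 0L) return(nrow(img))
  inner <- seq(min(idx), max(idx))
  sum(!bright[inner])
}

#' Simulate a longitudinal progressive-disease cohort
#'
#' Draws subject trajectories from the configuration distributions, schedules
#' annual scans with dropout, stops scanning at the event (no post-surgery
#' scans), ascertains events through the study end, renders one payload per
#' scan, and assembles the cohort manifest: one row per scan with subject id,
#' scan time, payload reference, grade, demographics and event time (`NA` =
#' censored; the censoring time of a subject is their last scan time).
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `cohort`: a list with `manifest` (data.frame),
#'   `features` (matrix, feature payloads by `payload_ref` rowname) or
#'   `images` (named list of matrices), and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  study_end <- cfg$n_visits - 1

  if (n == 0L) {
    manifest <- empty_manifest()
    return(structure(list(manifest = manifest, features = NULL,
                          images = NULL, config = cfg), class = "cohort"))
  }

  subject_id <- sprintf("S%04d", seq_len(n))
  progressor <- stats::runif(n) < cfg$prog_fraction
  s0 <- stats::runif(n, cfg$s0_range[1], cfg$s0_range[2])
  rate <- ifelse(progressor,
                 stats::rgamma(n, shape = cfg$rate_shape, rate = cfg$rate_rate),
                 0)
  age <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  ethnicity <- sample(c("A", "B", "C"), n, replace = TRUE,
                      prob = cfg$ethnicity_probs)
  bmi <- round(stats::rlnorm(n, cfg$bmi_meanlog, cfg$bmi_sdlog), 1)

  # imaging dropout: number of attended annual visits (baseline always kept)
  n_kept <- 1L + stats::rgeom(n, prob = max(cfg$dropout, 1e-12))
  n_kept <- pmin(n_kept, cfg$n_visits)
  if (cfg$dropout == 0) n_kept <- rep(cfg$n_visits, n)

  rows <- vector("list", n)
  payloads <- vector("list", n)
  scan_counter <- 0L
  for (i in seq_len(n)) {
    traj <- list(s0 = s0[i], rate = rate[i], theta = cfg$theta)
    ev <- event_time(traj)
    # events ascertained through the study end even after imaging dropout
    ev_obs <- if (!is.na(ev) && ev <= study_end) ev else NA_real_
    times <- seq(0, n_kept[i] - 1L)
    if (!is.na(ev)) times <- times[times < ev]
    if (length(times) == 0L) next  # event before baseline scan: excluded
    sev <- severity_at(traj, times)
    refs <- sprintf("%s_t%d", subject_id[i], seq_along(times) - 1L)
    pl <- lapply(seq_along(times), function(k) {
      render_scan(sev[k], cfg, seed = derive_seed(cfg$seed, scan_counter + k))
    })
    scan_counter <- scan_counter + length(times)
    names(pl) <- refs
    payloads[[i]] <- pl
    rows[[i]] <- data.frame(
      subject_id = subject_id[i], scan_time_years = times,
      payload_ref = refs, grade = grade_of(sev, cfg),
      age = age[i], sex = sex[i], ethnicity = ethnicity[i], bmi = bmi[i],
      event_time_years = ev_obs, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(manifest)) manifest <- empty_manifest()
  rownames(manifest) <- NULL
  payloads <- unlist(payloads, recursive = FALSE)

  features <- NULL
  images <- NULL
  if (cfg$payload == "feature") {
    features <- do.call(rbind, payloads)
    rownames(features) <- names(payloads)
    colnames(features) <- sprintf("f%02d", seq_len(ncol(features)))
  } else {
    images <- payloads
  }
  structure(list(manifest = manifest, features = features, images = images,
                 config = cfg), class = "cohort")
}

empty_manifest <- function() {
  data.frame(subject_id = character(), scan_time_years = numeric(),
             payload_ref = character(), grade = integer(),
             age = integer(), sex = character(), ethnicity = character(),
             bmi = numeric(), event_time_years = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.cohort <- function(x, ...) {
  m <- x$manifest
  n_sub <- length(unique(m$subject_id))
  n_case <- length(unique(m$subject_id[!is.na(m$event_time_years)]))
  cat(sprintf("cohort: %d scans, %d subjects (%d with observed event), %s payload\n",
              nrow(m), n_sub, n_case, x$config$payload))
  invisible(x)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Writes `manifest.csv` (censored event times as empty fields), feature
#' payloads as `features.csv` (one row per scan, keyed by `payload_ref`), and
#' image payloads as 8-bit grayscale PNGs under `payloads/`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  if (!is.null(cohort$features)) {
    df <- data.frame(payload_ref = rownames(cohort$features),
                     cohort$features, check.names = FALSE)
    utils::write.csv(df, file.path(dir, "features.csv"), row.names = FALSE)
  }
  if (!is.null(cohort$images)) {
    pd <- file.path(dir, "payloads")
    dir.create(pd, showWarnings = FALSE)
    for (ref in names(cohort$images)) {
      png::writePNG(cohort$images[[ref]], file.path(pd, paste0(ref, ".png")))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing `manifest.csv` and payload files.
#' @return A `cohort` object (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  features <- NULL
  images <- NULL
  fpath <- file.path(dir, "features.csv")
  if (file.exists(fpath)) {
    df <- utils::read.csv(fpath, stringsAsFactors = FALSE)
    features <- as.matrix(df[, -1, drop = FALSE])
    rownames(features) <- df$payload_ref
  }
  pd <- file.path(dir, "payloads")
  if (dir.exists(pd)) {
    files <- list.files(pd, pattern = "\\.png$", full.names = TRUE)
    images <- lapply(files, function(f) png::readPNG(f))
    names(images) <- sub("\\.png$", "", basename(files))
  }
  structure(list(manifest = manifest, features = features, images = images,
                 config = NULL), class = "cohort")
}
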