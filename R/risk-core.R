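#' Numerically stable logistic function
#'
#' Maps a real-valued score to a probability strictly inside (0, 1) via
#' \eqn{\sigma(z) = 1 / (1 + e^{-z})}. Scores are clipped to \eqn{\pm 500}
#' before exponentiation and the computation uses the sign-split branch form,
#' so no overflow occurs for any finite input.
#'
#' @param score Numeric vector of finite real-valued scores (logits).
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' sigmoid(0)            # 0.5
#' sigmoid(c(-2, 1, 30))
#' @export
sigmoid <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score))) {
    stop("`score` must be finite numeric", call. = FALSE)
  }
  z <- pmin(pmax(score, -500), 500)
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  # keep strictly inside (0, 1) even where the float result saturates
  pmin(pmax(out, PROB_FLOOR), 1 - PROB_FLOOR)
}

# smallest probability distance from {0, 1} preserved by the risk heads
PROB_FLOOR <- 1e-16

#' Supported risk formulations
#' @keywords internal
FORMULATIONS <- c("baseline", "riskform1", "riskform2")

match_formulation <- function(formulation) {
  if (length(formulation) != 1L || !is.character(formulation) ||
      !(tolower(formulation) %in% FORMULATIONS)) {
    stop("`formulation` must be one of: ", paste(FORMULATIONS, collapse = ", "),
         call. = FALSE)
  }
  tolower(formulation)
}

#' Compose paired-scan risks under a progressive risk formulation
#'
#' Turns two real-valued scores for sequential scans of the same subject into
#' a pair of event probabilities. The first-scan risk is always
#' \eqn{\hat{y}_1 = \sigma(s_1)}. The second-scan risk depends on the
#' formulation:
#' \describe{
#'   \item{baseline}{\eqn{\hat{y}_2 = \sigma(s_2)} — independent scans, no
#'     ordering guarantee.}
#'   \item{riskform1}{\eqn{\hat{y}_2 = 1 - (1-\sigma(s_1))(1-\sigma(s_2))} —
#'     a single scorer serves both scans; the second-scan score is positively
#'     related to risk.}
#'   \item{riskform2}{\eqn{\hat{y}_2 = 1 - (1-\sigma(s_1))\,\sigma(s_2)} —
#'     the second scan has its own scorer whose output is inversely related
#'     to risk.}
#' }
#' Both progressive formulations guarantee \eqn{\hat{y}_2 \ge \hat{y}_1} for
#' every pair of finite scores, because the no-event probability of the first
#' scan is multiplied by a factor in (0, 1).
#'
#' @param s1 Numeric vector, first-scan scores.
#' @param s2 Numeric vector, second-scan scores (same length as `s1`).
#' @param formulation One of `"baseline"`, `"riskform1"`, `"riskform2"`.
#' @return A data.frame with columns `y_hat_1`, `y_hat_2` (probabilities) and
#'   `formulation`.
#' @examples
#' compose_risks(0, 0, "riskform1")   # y_hat_2 = 0.75
#' compose_risks(0, 2, "riskform2")   # y_hat_2 = 1 - 0.5 * sigmoid(2)
#' @export
compose_risks <- function(s1, s2, formulation) {
  formulation <- match_formulation(formulation)
  if (length(s1) != length(s2)) {
    stop("`s1` and `s2` must have equal length", call. = FALSE)
  }
  p1 <- sigmoid(s1)
  p2 <- switch(formulation,
    baseline  = sigmoid(s2),
    riskform1 = 1 - (1 - p1) * (1 - sigmoid(s2)),
    riskform2 = 1 - (1 - p1) * sigmoid(s2)
  )
  # the composed product can saturate to exactly 1 in floats; pin it inside
  # (0, 1) without disturbing the ordering (p1 shares the same ceiling)
  p2 <- pmin(pmax(p2, PROB_FLOOR), 1 - PROB_FLOOR)
  data.frame(y_hat_1 = p1, y_hat_2 = p2, formulation = formulation,
             stringsAsFactors = FALSE)
}

# probability clamp for the log terms of the cross-entropy
BCE_EPS <- 1e-7

bce <- function(y, p) {
  p <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Paired binary cross-entropy loss
#'
#' The training loss for one (scan1, scan2) unit:
#' \eqn{L = \mathrm{BCE}(y_1, \hat{y}_1) + \mathrm{BCE}(y_2, \hat{y}_2)},
#' natural-logarithm cross-entropy with probabilities clamped at
#' \eqn{10^{-7}} from both ends. When no second scan exists (`y_hat_2` or
#' `y2` is `NULL`/`NA`) only the first-scan term is applied.
#'
#' @param y_hat_1,y_hat_2 Predicted probabilities in (0, 1); `y_hat_2` may be
#'   `NULL` or `NA` for single-scan units.
#' @param y1,y2 Binary labels in {0, 1}; `y2` may be `NULL`/`NA`.
#' @return Non-negative numeric vector of per-unit losses.
#' @examples
#' pair_loss(0.5, 0.75, y1 = 0, y2 = 1)  # -log(0.5) - log(0.75)
#' pair_loss(0.5, NULL, y1 = 1)          # -log(0.5)
#' @export
pair_loss <- function(y_hat_1, y_hat_2 = NULL, y1, y2 = NULL) {
  stopifnot(all(y1 %in% c(0, 1)))
  loss <- bce(y1, y_hat_1)
  if (!is.null(y_hat_2) && !is.null(y2)) {
    has2 <- !is.na(y_hat_2) & !is.na(y2)
    if (any(has2)) {
      stopifnot(all(y2[has2] %in% c(0, 1)))
      loss[has2] <- loss[has2] + bce(y2[has2], y_hat_2[has2])
    }
  }
  loss
}

#' Regularizer configuration
#'
#' Bundles the margin and weight shared by the two soft-constraint
#' comparators. The defaults (margin 2.0, gamma 1.0) are the tuned values
#' used with the margin-loss regularizer.
#'
#' @param margin Non-negative margin `m` on the score scale.
#' @param gamma Non-negative multiplicative weight of the penalty.
#' @param mode One of `"none"`, `"riskreg"`, `"conreg"`, `"both"`.
#' @return An object of class `regularizer_config`.
#' @export
regularizer_config <- function(margin = 2.0, gamma = 1.0,
                               mode = c("none", "riskreg", "conreg", "both")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(margin), length(margin) == 1L, margin >= 0,
            is.numeric(gamma), length(gamma) == 1L, gamma >= 0)
  structure(list(margin = margin, gamma = gamma, mode = mode),
            class = "regularizer_config")
}

#' @export
print.regularizer_config <- function(x, ...) {
  cat(sprintf("regularizer_config: mode=%s margin=%g gamma=%g\n",
              x$mode, x$margin, x$gamma))
  invisible(x)
}

#' Margin-loss risk regularizer (soft progressive constraint)
#'
#' Penalizes score pairs whose second-scan score does not exceed the
#' first-scan score by at least the margin:
#' \eqn{\gamma \, \max(0, m - (s_2 - s_1))}. It operates on raw scores
#' (logits), not probabilities — a margin of 2.0 is only meaningful on an
#' unbounded scale. The penalty is zero exactly on
#' \eqn{\{s_2 - s_1 \ge m\}}.
#'
#' @param s1,s2 Numeric score vectors for scan 1 and scan 2.
#' @param cfg A [regularizer_config()].
#' @return Non-negative numeric vector of penalties.
#' @examples
#' cfg <- regularizer_config(mode = "riskreg")
#' riskreg_penalty(0, 3, cfg)  # 0: constraint satisfied with slack
#' riskreg_penalty(0, 0, cfg)  # 2: full margin violated
#' @export
riskreg_penalty <- function(s1, s2, cfg = regularizer_config(mode = "riskreg")) {
  stopifnot(inherits(cfg, "regularizer_config"))
  if (!cfg$mode %in% c("riskreg", "both")) {
    stop("cfg$mode does not include the margin-loss regularizer", call. = FALSE)
  }
  cfg$gamma * pmax(0, cfg$margin - (s2 - s1))
}

#' Siamese contrastive regularizer on paired-scan embeddings
#'
#' The classic contrastive (Hadsell-style) loss on final-layer embeddings of
#' the two scans, with "different label" as the dissimilar condition: with
#' \eqn{d = \lVert h_1 - h_2 \rVert_2} and \eqn{s = 1} when \eqn{y_1 \ne y_2},
#' returns \eqn{\gamma\,[(1-s)\,d^2 + s\,\max(0, m - d)^2]}. Same-label pairs
#' are pulled together; pairs that straddle the event are pushed at least the
#' margin apart.
#'
#' @param h1,h2 Numeric embedding vectors of equal dimension, or matrices with
#'   one embedding per row.
#' @param y1,y2 Binary labels of the two scans.
#' @param cfg A [regularizer_config()].
#' @return Non-negative numeric penalty (vector when matrices are given).
#' @examples
#' cfg <- regularizer_config(mode = "conreg")
#' conreg_penalty(c(1, 0), c(1, 0), 0, 1, cfg)  # max(0, 2)^2 = 4
#' @export
conreg_penalty <- function(h1, h2, y1, y2,
                           cfg = regularizer_config(mode = "conreg")) {
  stopifnot(inherits(cfg, "regularizer_config"))
  if (!cfg$mode %in% c("conreg", "both")) {
    stop("cfg$mode does not include the contrastive regularizer", call. = FALSE)
  }
  if (is.null(dim(h1))) h1 <- matrix(h1, nrow = 1)
  if (is.null(dim(h2))) h2 <- matrix(h2, nrow = 1)
  if (!all(dim(h1) == dim(h2))) {
    stop("embedding dimensions differ", call. = FALSE)
  }
  d <- sqrt(rowSums((h1 - h2)^2))
  dissim <- as.numeric(y1 != y2)
  cfg$gamma * ((1 - dissim) * d^2 + dissim * pmax(0, cfg$margin - d)^2)
}
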