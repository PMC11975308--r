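#' Assemble paired training tensors from pairs and payload features
#'
#' Converts a [select_training_scans()] table plus a payload feature matrix
#' into the dense arrays the trainer consumes. Singles (no second scan) get
#' `has2 = FALSE` and contribute only the first-scan loss term.
#'
#' @param pairs Data.frame from [select_training_scans()].
#' @param features Numeric matrix of payload features with `payload_ref`
#'   rownames (see [cohort_features()]).
#' @return A list of class `pair_set`: `X1`, `X2` (matrices, `X2` rows are 0
#'   for singles), `y1`, `y2`, `has2`, `subject_id`, `grade1`, `grade2`,
#'   `set_id`, `horizon`.
#' @export
pair_tensors <- function(pairs, features) {
  missing_ref <- setdiff(c(pairs$payload1, stats::na.omit(pairs$payload2)),
                         rownames(features))
  if (length(missing_ref) > 0) {
    stop("payload reference(s) not found in features: ",
         paste(utils::head(missing_ref, 3), collapse = ", "), call. = FALSE)
  }
  has2 <- !is.na(pairs$payload2)
  X1 <- features[pairs$payload1, , drop = FALSE]
  X2 <- matrix(0, nrow(pairs), ncol(features))
  X2[has2, ] <- features[pairs$payload2[has2], , drop = FALSE]
  structure(list(X1 = X1, X2 = X2, y1 = pairs$y1, y2 = pairs$y2,
                 has2 = has2, subject_id = pairs$subject_id,
                 grade1 = pairs$grade1, grade2 = pairs$grade2,
                 set_id = pairs$set_id,
                 horizon = pairs$horizon[1]),
            class = "pair_set")
}

#' Payload feature matrix of a cohort
#'
#' Feature cohorts return their feature matrix directly. Image cohorts are
#' reduced by a fixed (untrained) extractor: the measured band gap fraction,
#' the mean intensity, and the row-mean profile pooled into six bands —
#' enough for the small reference scorer to learn from.
#'
#' @param cohort A `cohort` object.
#' @return Numeric matrix, one row per scan, rownames = `payload_ref`.
#' @export
cohort_features <- function(cohort) {
  if (!is.null(cohort$features)) return(cohort$features)
  stopifnot(!is.null(cohort$images))
  feats <- t(vapply(cohort$images, image_features, numeric(8)))
  rownames(feats) <- names(cohort$images)
  feats
}

image_features <- function(img) {
  prof <- rowMeans(img)
  pooled <- vapply(split(prof, cut(seq_along(prof), 6, labels = FALSE)),
                   mean, numeric(1))
  c(image_band_gap(img) / nrow(img), mean(img), pooled)
}

#' Reference feature scorer: a single-hidden-layer perceptron
#'
#' The trainable map from a payload feature vector to one real-valued score,
#' standing in for the large imaging backbones the method is normally paired
#' with. tanh hidden layer, linear output; parameters initialized at scale
#' `1/sqrt(fan-in)`. Fitting is by minibatch Adam with analytically derived
#' gradients. Inference is deterministic given fixed parameters.
#'
#' @param input_dim Payload feature dimension.
#' @param hidden Hidden width (default 8).
#' @param seed Integer seed for initialization.
#' @return A list of parameter arrays of class `mlp_scorer`.
#' @export
mlp_scorer <- function(input_dim, hidden = 8, seed = 1L) {
  set.seed(seed)
  structure(list(
    W1 = matrix(stats::rnorm(input_dim * hidden, 0, 1 / sqrt(input_dim)),
                input_dim, hidden),
    b1 = numeric(hidden),
    w2 = stats::rnorm(hidden, 0, 1 / sqrt(hidden)),
    b2 = 0), class = "mlp_scorer")
}

scorer_forward <- function(par, X) {
  A <- sweep(X %*% par$W1, 2, par$b1, "+")
  H <- tanh(A)
  list(H = H, s = drop(H %*% par$w2) + par$b2)
}

#' Score payloads with a fitted scorer
#' @param scorer An `mlp_scorer`.
#' @param X Feature matrix (one payload per row).
#' @return Numeric vector of real-valued scores.
#' @export
scorer_score <- function(scorer, X) {
  scorer_forward(scorer, X)$s
}

# backprop from per-sample score gradients (and optional embedding
# gradients) to parameter gradients, averaged over n_total samples
scorer_backward <- function(par, X, H, ds, n_total, dH_extra = NULL) {
  dH <- outer(ds, par$w2)
  if (!is.null(dH_extra)) dH <- dH + dH_extra
  dA <- dH * (1 - H^2)
  list(W1 = crossprod(X, dA) / n_total,
       b1 = colSums(dA) / n_total,
       w2 = drop(crossprod(H, ds)) / n_total,
       b2 = sum(ds) / n_total)
}

zero_like <- function(par) lapply(par, function(p) p * 0)

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grad)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Training hyperparameters
#'
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty coefficient on weight matrices.
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param hidden Hidden width of the reference scorer.
#' @return A named list.
#' @export
train_hyper <- function(lr = 0.05, weight_decay = 1e-4, epochs = 60,
                        batch_size = 64, hidden = 8) {
  list(lr = lr, weight_decay = weight_decay, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), hidden = as.integer(hidden))
}

# loss (mean per unit) of a model on a pair_set, penalties included
model_loss <- function(par_f, par_g, data, formulation, reg) {
  s1 <- scorer_forward(par_f, data$X1)$s
  fwd2 <- if (formulation == "riskform2") par_g else par_f
  s2 <- scorer_forward(fwd2, data$X2)$s
  risks <- compose_risks(s1, s2, formulation)
  y2 <- ifelse(data$has2, data$y2, NA_integer_)
  yh2 <- ifelse(data$has2, risks$y_hat_2, NA_real_)
  loss <- pair_loss(risks$y_hat_1, yh2, data$y1, y2)
  pen <- 0
  if (reg$mode %in% c("riskreg", "both") && any(data$has2)) {
    pen <- pen + sum(riskreg_penalty(s1[data$has2], s2[data$has2], reg))
  }
  if (reg$mode %in% c("conreg", "both") && any(data$has2)) {
    H1 <- scorer_forward(par_f, data$X1)$H
    H2 <- scorer_forward(par_f, data$X2)$H
    i <- data$has2
    pen <- pen + sum(conreg_penalty(H1[i, , drop = FALSE],
                                    H2[i, , drop = FALSE],
                                    data$y1[i], data$y2[i], reg))
  }
  (sum(loss) + pen) / length(data$y1)
}

clamp01 <- function(p) pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)

#' Fit scorers for one cross-validation assignment
#'
#' Minimizes the mean paired cross-entropy (plus any configured soft-
#' constraint penalty) over mixed single/paired samples by minibatch Adam.
#' Single-scan samples contribute only the first-scan term and update only
#' the primary scorer `f`; the second scorer `g` (present only under
#' `riskform2`) receives gradients only from samples with two scans. After
#' each epoch the model is checkpointed when its validation AUROC (pooled
#' over scan 1 and scan 2 predictions; negative mean loss when the
#' validation set has one class) improves; the best checkpoint is returned.
#' Deterministic given `seed`.
#'
#' @param train_data,val_data `pair_set` objects (see [pair_tensors()]).
#' @param formulation `"baseline"`, `"riskform1"` or `"riskform2"`.
#' @param reg A [regularizer_config()]; modes other than `"none"` are only
#'   meaningful with the baseline formulation.
#' @param hyper A [train_hyper()] list.
#' @param seed Integer seed (initialization + batch shuffling).
#' @return An object of class `fitted_model`: scorer(s), formulation,
#'   regularizer config, hyperparameters, seed, validation metric, and the
#'   training loss at initialization and after fitting.
#' @export
train_fold <- function(train_data, val_data = NULL, formulation = "baseline",
                       reg = regularizer_config(), hyper = train_hyper(),
                       seed = 1L) {
  formulation <- match_formulation(formulation)
  stopifnot(inherits(train_data, "pair_set"))
  labels_all <- c(train_data$y1, train_data$y2[train_data$has2])
  if (length(unique(labels_all)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (reg$mode != "none" && formulation != "baseline") {
    stop("soft-constraint regularizers apply to the baseline formulation only",
         call. = FALSE)
  }
  d <- ncol(train_data$X1)
  par_f <- mlp_scorer(d, hyper$hidden, seed = seed)
  par_g <- if (formulation == "riskform2") {
    mlp_scorer(d, hyper$hidden, seed = derive_seed(seed, 1L))
  } else NULL

  loss_init <- model_loss(par_f, par_g, train_data, formulation, reg)
  best <- list(par_f = par_f, par_g = par_g, metric = -Inf)
  n <- length(train_data$y1)
  state_f <- list(m = zero_like(par_f), v = zero_like(par_f))
  state_g <- if (!is.null(par_g)) list(m = zero_like(par_g), v = zero_like(par_g))
  step <- 0L
  set.seed(derive_seed(seed, 2L))
  for (epoch in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = hyper$batch_size)
    for (b0 in starts) {
      idx <- ord[b0:min(b0 + hyper$batch_size - 1L, n)]
      nb <- length(idx)
      X1 <- train_data$X1[idx, , drop = FALSE]
      X2 <- train_data$X2[idx, , drop = FALSE]
      y1 <- train_data$y1[idx]
      y2 <- train_data$y2[idx]
      has2 <- train_data$has2[idx]

      f1 <- scorer_forward(par_f, X1)
      fwd2_par <- if (formulation == "riskform2") par_g else par_f
      f2 <- scorer_forward(fwd2_par, X2)
      p1 <- sigmoid(f1$s)
      ds1 <- p1 - y1                       # scan-1 BCE term, all samples
      ds2 <- numeric(nb)
      dH1_extra <- NULL
      if (any(has2)) {
        i <- which(has2)
        p2 <- sigmoid(f2$s[i])
        if (formulation == "baseline") {
          ds2[i] <- p2 - y2[i]
        } else if (formulation == "riskform1") {
          yh2 <- clamp01(1 - (1 - p1[i]) * (1 - p2))
          dL <- (yh2 - y2[i]) / (yh2 * (1 - yh2))
          ds1[i] <- ds1[i] + dL * p1[i] * (1 - p1[i]) * (1 - p2)
          ds2[i] <- dL * (1 - p1[i]) * p2 * (1 - p2)
        } else {
          yh2 <- clamp01(1 - (1 - p1[i]) * p2)
          dL <- (yh2 - y2[i]) / (yh2 * (1 - yh2))
          ds1[i] <- ds1[i] + dL * p1[i] * (1 - p1[i]) * p2
          ds2[i] <- -dL * (1 - p1[i]) * p2 * (1 - p2)
        }
        if (reg$mode %in% c("riskreg", "both")) {
          viol <- (reg$margin - (f2$s[i] - f1$s[i])) > 0
          ds1[i] <- ds1[i] + reg$gamma * viol
          ds2[i] <- ds2[i] - reg$gamma * viol
        }
        if (reg$mode %in% c("conreg", "both")) {
          D <- f1$H[i, , drop = FALSE] - f2$H[i, , drop = FALSE]
          dist <- sqrt(rowSums(D^2))
          dissim <- y1[i] != y2[i]
          coef <- ifelse(dissim,
                         ifelse(dist > 0 & dist < reg$margin,
                                -2 * reg$gamma * (reg$margin - dist) / dist, 0),
                         2 * reg$gamma)
          dH1_extra <- matrix(0, nb, ncol(f1$H))
          dH1_extra[i, ] <- D * coef
        }
      }

      grad_f <- scorer_backward(par_f, X1, f1$H, ds1, nb,
                                dH_extra = dH1_extra)
      dH2_extra <- if (!is.null(dH1_extra)) -dH1_extra
      if (formulation == "riskform2") {
        grad_g <- scorer_backward(par_g, X2, f2$H, ds2, nb)
      } else {
        grad_f <- add_grads(grad_f,
                            scorer_backward(par_f, X2, f2$H, ds2, nb,
                                            dH_extra = dH2_extra))
        grad_g <- NULL
      }
      if (hyper$weight_decay > 0) {
        grad_f$W1 <- grad_f$W1 + hyper$weight_decay * par_f$W1
        grad_f$w2 <- grad_f$w2 + hyper$weight_decay * par_f$w2
        if (!is.null(grad_g)) {
          grad_g$W1 <- grad_g$W1 + hyper$weight_decay * par_g$W1
          grad_g$w2 <- grad_g$w2 + hyper$weight_decay * par_g$w2
        }
      }
      step <- step + 1L
      up <- adam_step(par_f, grad_f, state_f, hyper$lr, step)
      par_f <- up$par; state_f <- up$state
      # g learns only from samples with two scans
      if (!is.null(grad_g) && any(has2)) {
        up <- adam_step(par_g, grad_g, state_g, hyper$lr, step)
        par_g <- up$par; state_g <- up$state
      }
    }
    metric <- validation_metric(par_f, par_g, val_data, formulation, reg,
                                train_data)
    if (metric > best$metric) {
      best <- list(par_f = par_f, par_g = par_g, metric = metric)
    }
  }
  if (hyper$epochs == 0L) best <- list(par_f = par_f, par_g = par_g,
                                       metric = NA_real_)
  model <- structure(list(formulation = formulation, scorer_f = best$par_f,
                          scorer_g = best$par_g, reg = reg, hyper = hyper,
                          seed = as.integer(seed),
                          val_metric = best$metric,
                          loss_init = loss_init), class = "fitted_model")
  model$loss_final <- model_loss(model$scorer_f, model$scorer_g, train_data,
                                 formulation, reg)
  model
}

validation_metric <- function(par_f, par_g, val_data, formulation, reg,
                              train_data) {
  data <- if (is.null(val_data)) train_data else val_data
  s1 <- scorer_forward(par_f, data$X1)$s
  fwd2 <- if (formulation == "riskform2") par_g else par_f
  s2 <- scorer_forward(fwd2, data$X2)$s
  risks <- compose_risks(s1, s2, formulation)
  lab <- c(data$y1, data$y2[data$has2])
  sc <- c(risks$y_hat_1, risks$y_hat_2[data$has2])
  if (length(unique(lab)) < 2L) {
    return(-model_loss(par_f, par_g, data, formulation, reg))
  }
  auroc(lab, sc)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model: %s, val metric %.4f, train loss %.4f -> %.4f\n",
              x$formulation, x$val_metric, x$loss_init, x$loss_final))
  invisible(x)
}

#' Scan-level risk predictions of one fitted model
#'
#' The first-scan risk is the sigmoid of the primary scorer's output; the
#' second-scan risk (when present) is composed with the model's formulation,
#' so under the progressive formulations it can never fall below the
#' first-scan risk.
#'
#' @param model A [train_fold()] result.
#' @param data A `pair_set`.
#' @return Data.frame with one row per scan: `subject_id`, `scan_index`
#'   (1 or 2), `risk`, `label`, `grade`, `set_id`, `horizon`.
#' @export
predict_scan_risks <- function(model, data) {
  stopifnot(inherits(model, "fitted_model"), inherits(data, "pair_set"))
  s1 <- scorer_score(model$scorer_f, data$X1)
  par2 <- if (model$formulation == "riskform2") model$scorer_g else model$scorer_f
  s2 <- scorer_score(par2, data$X2)
  risks <- compose_risks(s1, s2, model$formulation)
  scan1 <- data.frame(subject_id = data$subject_id, scan_index = 1L,
                      risk = risks$y_hat_1, label = data$y1,
                      grade = data$grade1, set_id = data$set_id,
                      horizon = data$horizon, stringsAsFactors = FALSE)
  i <- data$has2
  scan2 <- data.frame(subject_id = data$subject_id[i], scan_index = 2L,
                      risk = risks$y_hat_2[i], label = data$y2[i],
                      grade = data$grade2[i], set_id = data$set_id[i],
                      horizon = data$horizon, stringsAsFactors = FALSE)
  out <- rbind(scan1, scan2)
  rownames(out) <- NULL
  out
}

#' Ensemble scan-level predictions over several fitted models
#'
#' Averages per-scan risks (probabilities, not logits) over the member
#' models. Averaging preserves the progressive ordering: when every member
#' satisfies risk2 >= risk1 for a pair, so does the ensemble.
#'
#' @param models Non-empty list of `fitted_model`s sharing one formulation.
#' @param data A `pair_set`.
#' @return Data.frame as [predict_scan_risks()] plus `n_members`.
#' @export
ensemble_predict <- function(models, data) {
  if (length(models) == 0L) stop("empty model list", call. = FALSE)
  forms <- unique(vapply(models, function(m) m$formulation, character(1)))
  if (length(forms) != 1L) {
    stop("all ensemble members must share one formulation", call. = FALSE)
  }
  preds <- lapply(models, predict_scan_risks, data = data)
  out <- preds[[1]]
  risks <- sapply(preds, function(p) p$risk)
  out$risk <- if (is.matrix(risks)) rowMeans(risks) else mean(risks)
  out$n_members <- length(models)
  out
}

#' Write a fitted model as a JSON checkpoint with metadata
#'
#' Parameters and metadata (formulation, hyperparameters, regularizer
#' configuration, seed, fold identity) are stored together in one JSON
#' document.
#'
#' @param model A `fitted_model`.
#' @param path Output path.
#' @param fold Optional fold identity to record.
#' @export
write_checkpoint <- function(model, path, fold = NULL) {
  doc <- list(
    format = "progrisk-checkpoint-1",
    formulation = model$formulation,
    hyper = model$hyper,
    reg = unclass(model$reg),
    seed = model$seed,
    fold = fold,
    val_metric = model$val_metric,
    scorer_f = lapply(unclass(model$scorer_f), as.vector),
    scorer_f_dim = dim(model$scorer_f$W1),
    scorer_g = if (!is.null(model$scorer_g))
      lapply(unclass(model$scorer_g), as.vector),
    scorer_g_dim = dim(model$scorer_g$W1))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a checkpoint written by [write_checkpoint()]
#' @param path Checkpoint path.
#' @return A `fitted_model`.
#' @export
read_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(sc, dm) {
    if (is.null(sc) || length(sc) == 0) return(NULL)
    structure(list(W1 = matrix(sc$W1, dm[1], dm[2]), b1 = sc$b1,
                   w2 = sc$w2, b2 = sc$b2), class = "mlp_scorer")
  }
  structure(list(formulation = doc$formulation,
                 scorer_f = rebuild(doc$scorer_f, doc$scorer_f_dim),
                 scorer_g = rebuild(doc$scorer_g, doc$scorer_g_dim),
                 reg = do.call(regularizer_config, as.list(doc$reg)),
                 hyper = do.call(train_hyper, as.list(doc$hyper)),
                 seed = doc$seed, val_metric = doc$val_metric),
            class = "fitted_model")
}
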