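# The survival network: masked VNN trunk -> concat clinical -> two-layer
# dense head -> scalar risk; trained by minimizing the negative Cox
# partial log-likelihood with AdamW. Plus the comparison baselines: a
# width-matched dense network and the linear proportional-hazards model.

#' Default hyperparameters
#' @param ... Overrides for any of `learning_rate`, `weight_decay`,
#'   `batch_size`, `epochs`, `dropout_rate`, `seed`.
#' @return A `hyperparams` list.
#' @export
hyperparams <- function(...) {
  hp <- list(learning_rate = 1e-2, weight_decay = 1e-4, batch_size = 64,
             epochs = 100, dropout_rate = 0.2, seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(hp))
  if (length(unknown) > 0) stopf("unknown hyperparameter(s): %s",
                                 paste(unknown, collapse = ", "))
  hp[names(ov)] <- ov
  stopifnot(hp$learning_rate > 0, hp$weight_decay >= 0, hp$batch_size >= 1,
            hp$epochs >= 0, hp$dropout_rate >= 0, hp$dropout_rate < 1)
  structure(hp, class = "hyperparams")
}

#' Default hyperparameter grid for cross-validated search
#'
#' Learning rate {1e-2, 1e-3} x weight decay {1e-2, 1e-4} x batch size
#' {64, n} at 100 epochs, dropout 0.2.
#'
#' @param n Cohort size (for the full-batch grid point).
#' @return List of `hyperparams`.
#' @export
default_grid <- function(n) {
  grid <- list()
  for (lr in c(1e-2, 1e-3)) {
    for (wd in c(1e-2, 1e-4)) {
      for (bs in unique(c(64, n))) {
        grid[[length(grid) + 1]] <- hyperparams(learning_rate = lr,
                                                weight_decay = wd,
                                                batch_size = bs)
      }
    }
  }
  grid
}

#' Initialize a masked survival network
#'
#' Weights are drawn from a symmetric scaled-uniform (Glorot) distribution
#' under `seed`; masked-out positions are exactly zero and skip-through
#' identity channels exactly one; all biases start at zero.
#'
#' @param spec A `vnn_spec` from [build_masks()]/[build_vnn_spec()].
#' @param n_clinical Number of clinical covariates concatenated at the head.
#' @param head_width Hidden width of the two-layer dense head.
#' @param dropout Dropout rate in \[0, 1) applied to pathway and head
#'   units during training.
#' @param activation `"tanh"` (default), `"relu"` or `"identity"`.
#' @param seed Integer seed for the initialization.
#' @return A `vnn_model`.
#' @export
init_model <- function(spec, n_clinical = 0L, head_width = 64L,
                       dropout = 0.2, activation = "tanh", seed = 1L) {
  stopifnot(inherits(spec, "vnn_spec"), head_width >= 1)
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  act_fun(activation)  # validates the name
  with_seed(seed, {
    vnn <- lapply(spec$layers, function(ls) {
      list(W = glorot_init(ls$mask, ls$trainable),
           b = numeric(length(ls$out_names)))
    })
    root <- NULL
    if (spec$root_mode == "dense") {
      s <- sqrt(6 / (length(spec$root_units) + spec$root_width))
      root <- list(W = matrix(stats::runif(length(spec$root_units) *
                                             spec$root_width, -s, s),
                              length(spec$root_units), spec$root_width),
                   b = numeric(spec$root_width))
    }
    in1 <- spec$root_width + n_clinical
    s1 <- sqrt(6 / (in1 + head_width))
    s2 <- sqrt(6 / (head_width + 1))
    head <- list(W1 = matrix(stats::runif(in1 * head_width, -s1, s1),
                             in1, head_width),
                 b1 = numeric(head_width),
                 W2 = matrix(stats::runif(head_width, -s2, s2), head_width, 1),
                 b2 = 0)
    structure(list(spec = spec, vnn = vnn, root = root, head = head,
                   n_clinical = as.integer(n_clinical),
                   head_width = as.integer(head_width),
                   dropout = dropout, activation = activation,
                   seed = as.integer(seed)),
              class = "vnn_model")
  })
}

#' @export
print.vnn_model <- function(x, ...) {
  cat(sprintf("vnn_model: %d gene inputs + %d clinical -> root %d -> head %d -> risk\n",
              length(x$spec$feature_order), x$n_clinical, x$spec$root_width,
              x$head_width))
  cat(sprintf("  activation %s, dropout %.2f\n", x$activation, x$dropout))
  invisible(x)
}

cohort_inputs <- function(model, cohort) {
  want <- model$spec$feature_order
  have <- cohort$feature_names
  if (!setequal(want, have) || model$n_clinical != ncol(cohort$clinical)) {
    stopf("cohort features do not match the model: missing [%s], extra [%s], clinical %d vs %d",
          paste(setdiff(want, have), collapse = ", "),
          paste(setdiff(have, want), collapse = ", "),
          ncol(cohort$clinical), model$n_clinical)
  }
  list(X = cohort$features[, want, drop = FALSE],
       C = cohort$clinical)
}

#' Predict per-patient risk scores
#'
#' Deterministic forward pass (dropout disabled unless `training = TRUE`,
#' in which case `dropout_masks` drawn from the current RNG are applied).
#'
#' @param model A `vnn_model`.
#' @param cohort A `cohort_table` whose features match the model's spec.
#' @param training Apply dropout (used internally during fitting)?
#' @return data.frame `risk_table`: `patient_id`, `risk`.
#' @export
predict_risk <- function(model, cohort, training = FALSE) {
  inp <- cohort_inputs(model, cohort)
  dm <- if (training) draw_dropout_masks(model, n_patients(cohort)) else NULL
  fw <- nn_forward(model, inp$X, inp$C, dropout_masks = dm)
  structure(data.frame(patient_id = cohort$patient_id, risk = fw$risk,
                       stringsAsFactors = FALSE),
            class = c("risk_table", "data.frame"))
}

#' Negative Cox partial log-likelihood
#'
#' The log partial likelihood is
#' `sum over events i of (r_i - log sum over j in R(t_i) of exp(r_j))`
#' with risk set `R(t_i) = {j : t_j >= t_i}` (tied times included,
#' Breslow convention). This function returns its negative, the quantity
#' minimized during training, computed with log-sum-exp stabilization.
#'
#' @param risks Numeric risk scores (or a `risk_table`).
#' @param time Positive times.
#' @param event 0/1 event indicators; at least one event required.
#' @return Scalar loss (negative log partial likelihood).
#' @export
cox_loss <- function(risks, time, event) {
  r <- if (is.data.frame(risks)) risks$risk else risks
  stopifnot(length(r) == length(time), length(time) == length(event))
  if (sum(event) == 0) stopf("partial likelihood undefined without events")
  if (any(time <= 0)) stopf("times must be positive")
  ll <- cox_ll_parts(r, time, event)
  -sum(r[event == 1] - ll$logS[event == 1])
}

# Shared machinery: per-patient log S(t_i) = log sum_{t_j >= t_i} exp(r_j)
# and the cumulative event/S sums the gradient needs.
cox_ll_parts <- function(r, time, event) {
  n <- length(r)
  m <- max(r)
  ord <- order(time, decreasing = TRUE)  # descending time
  er <- exp(r[ord] - m)
  cs <- cumsum(er)
  t_s <- time[ord]
  # tie blocks share the risk-set sum of the whole block
  block_end <- stats::ave(seq_len(n), match(t_s, unique(t_s)), FUN = max)
  S_sorted <- cs[block_end]
  logS <- numeric(n)
  logS[ord] <- log(S_sorted) + m
  S <- numeric(n)
  S[ord] <- S_sorted  # scaled by exp(-m); used only in ratios
  list(logS = logS, S_scaled = S, scale = m)
}

#' Gradient of [cox_loss()] with respect to the risk scores
#' @inheritParams cox_loss
#' @return Numeric vector, `d loss / d risk_k`.
#' @export
cox_loss_grad <- function(risks, time, event) {
  r <- if (is.data.frame(risks)) risks$risk else risks
  if (sum(event) == 0) stopf("partial likelihood undefined without events")
  parts <- cox_ll_parts(r, time, event)
  n <- length(r)
  asc <- order(time)  # ascending
  contrib <- (event[asc] == 1) / parts$S_scaled[asc]
  cum <- cumsum(contrib)
  t_a <- time[asc]
  block_end <- stats::ave(seq_len(n), match(t_a, unique(t_a)), FUN = max)
  A <- numeric(n)
  A[asc] <- cum[block_end]
  -(as.numeric(event == 1) - exp(r - parts$scale) * A)
}

#' Train a masked survival network
#'
#' AdamW with decoupled weight decay; dropout on pathway and head units;
#' mini-batches drawn by seed-controlled shuffling each epoch, with the
#' partial likelihood evaluated within each batch (a batch that happens
#' to contain no events is skipped with a notice). Masked-out weight
#' positions remain exactly zero after every update.
#'
#' @param model A `vnn_model` (its `dropout` field governs training).
#' @param cohort A `cohort_table` with at least 2 events.
#' @param hp A [hyperparams()] object.
#' @param verbose Print per-epoch loss?
#' @return List: `model` (trained), `history` (per-epoch full-cohort loss).
#' @export
train_model <- function(model, cohort, hp = hyperparams(), verbose = FALSE) {
  if (sum(cohort$event) < 2) stopf("need at least 2 events to train")
  inp <- cohort_inputs(model, cohort)
  n <- n_patients(cohort)
  state <- new_adamw_state(model)
  history <- numeric(hp$epochs)
  skipped <- 0L
  with_seed(hp$seed, {
    for (ep in seq_len(hp$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = hp$batch_size)
      for (s in starts) {
        b <- idx[s:min(s + hp$batch_size - 1, n)]
        if (sum(cohort$event[b]) == 0) {
          skipped <- skipped + 1L
          next
        }
        Xb <- inp$X[b, , drop = FALSE]
        Cb <- inp$C[b, , drop = FALSE]
        dm <- draw_dropout_masks(model, length(b))
        fw <- nn_forward(model, Xb, Cb, dropout_masks = dm, keep = TRUE)
        dr <- cox_loss_grad(fw$risk, cohort$time[b], cohort$event[b])
        gr <- nn_backward(model, fw, Xb, Cb, dr, dropout_masks = dm)
        stp <- adamw_step(model, gr, state, hp$learning_rate, hp$weight_decay)
        model <- stp$model
        state <- stp$state
      }
      ev <- nn_forward(model, inp$X, inp$C)
      history[ep] <- cox_loss(ev$risk, cohort$time, cohort$event)
      if (verbose) message(sprintf("epoch %3d  loss %.6f", ep, history[ep]))
    }
  })
  if (skipped > 0) {
    message(sprintf("train_model: skipped %d event-free batch(es)", skipped))
  }
  list(model = model, history = history)
}

stratified_folds <- function(event, k, seed) {
  n <- length(event)
  if (k < 2 || n < k) stopf("need 2 <= k <= n")
  fold <- integer(n)
  with_seed(seed, {
    for (grp in c(1, 0)) {
      ids <- sample(which(event == grp))
      fold[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  if (any(tabulate(fold[event == 1], k) == 0)) {
    stopf("cannot form %d folds that each contain an event (only %d events)",
          k, sum(event))
  }
  fold
}

subset_cohort <- function(cohort, idx) {
  cohort_table(cohort$patient_id[idx],
               cohort$features[idx, , drop = FALSE],
               cohort$clinical[idx, , drop = FALSE],
               cohort$time[idx], cohort$event[idx])
}

#' K-fold cross-validation with hyperparameter search
#'
#' Folds are split once under `seed`, stratified by event status so that
#' every fold contains events. Each grid point is trained on k-1 folds
#' and scored by held-out concordance; the point with the highest mean
#' held-out C-index wins.
#'
#' @param cohort A `cohort_table`.
#' @param spec A `vnn_spec` (or `NULL` with `model_builder` supplied).
#' @param grid List of [hyperparams()] (default [default_grid()]).
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling folds and fits.
#' @param head_width,dropout,activation Passed to [init_model()].
#' @param model_builder Optional `function(spec, n_clinical, seed)`
#'   overriding [init_model()] (used for the dense baseline).
#' @return A `cv_report`: `fold_scores` (chosen point), `chosen`
#'   (hyperparams), `grid_means`, `folds`, `histories`.
#' @export
cross_validate <- function(cohort, spec, grid = NULL, k = 10L, seed = 1L,
                           head_width = 64L, dropout = 0.2,
                           activation = "tanh", model_builder = NULL) {
  n <- n_patients(cohort)
  grid <- grid %||% default_grid(n)
  fold <- stratified_folds(cohort$event, k, seed)
  seeds <- derive_seeds(seed, length(grid) * k + 1)
  builder <- model_builder %||% function(spec, n_clinical, s) {
    init_model(spec, n_clinical, head_width = head_width, dropout = dropout,
               activation = activation, seed = s)
  }
  scores <- matrix(NA_real_, length(grid), k)
  histories <- vector("list", length(grid))
  si <- 0
  for (g in seq_along(grid)) {
    hp <- grid[[g]]
    histories[[g]] <- vector("list", k)
    for (f in seq_len(k)) {
      si <- si + 1
      tr <- subset_cohort(cohort, fold != f)
      te <- subset_cohort(cohort, fold == f)
      hp_f <- hp
      hp_f$seed <- seeds[si]
      hp_f$batch_size <- min(hp$batch_size, n_patients(tr))
      mdl <- builder(spec, ncol(cohort$clinical), seeds[si])
      fit <- train_model(mdl, tr, hp_f)
      risks <- predict_risk(fit$model, te)
      scores[g, f] <- c_index(risks, te$time, te$event)$value
      histories[[g]][[f]] <- fit$history
    }
  }
  means <- rowMeans(scores)
  best <- which.max(means)
  structure(list(fold_scores = scores[best, ],
                 chosen = grid[[best]],
                 grid_means = means,
                 grid = grid,
                 all_scores = scores,
                 folds = fold,
                 histories = histories[[best]]),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d folds, mean held-out C-index %.4f (sd %.4f)\n",
              length(x$fold_scores), mean(x$fold_scores),
              stats::sd(x$fold_scores)))
  cat(sprintf("  chosen: lr %.4g, wd %.4g, batch %d, epochs %d, dropout %.2f\n",
              x$chosen$learning_rate, x$chosen$weight_decay,
              x$chosen$batch_size, x$chosen$epochs, x$chosen$dropout_rate))
  invisible(x)
}

#' Dense-spec counterpart of a masked spec
#'
#' Same layer count and per-layer widths as the masked network, but with
#' every connection present and trainable (no biological constraint).
#' Used by the dense baseline.
#'
#' @param spec A `vnn_spec`.
#' @return A `vnn_spec` with full masks.
#' @export
dense_spec_like <- function(spec) {
  dense <- spec
  dense$layers <- lapply(spec$layers, function(ls) {
    m <- matrix(1, nrow(ls$mask), ncol(ls$mask), dimnames = dimnames(ls$mask))
    list(in_names = ls$in_names, out_names = ls$out_names,
         mask = m, trainable = m == 1,
         is_pathway = rep(TRUE, length(ls$out_names)))
  })
  dense
}

#' Cross-validate the width-matched dense baseline
#'
#' A fully connected network with the same number of hidden layers and
#' the same per-layer widths as the masked network; its parameter count
#' is therefore at least the masked model's nonzero count.
#'
#' @inheritParams cross_validate
#' @return A `cv_report`.
#' @export
baseline_dense <- function(cohort, spec, grid = NULL, k = 10L, seed = 1L,
                           head_width = 64L, dropout = 0.2,
                           activation = "tanh") {
  dense <- dense_spec_like(spec)
  cross_validate(cohort, dense, grid = grid, k = k, seed = seed,
                 head_width = head_width, dropout = dropout,
                 activation = activation)
}

#' Linear proportional-hazards baseline
#'
#' Fits the linear Cox model on all genetic + clinical columns by
#' maximizing the same partial likelihood (via `survival::coxph`);
#' risk = the linear predictor. Constant columns are dropped with a
#' notice.
#'
#' @param cohort A `cohort_table`.
#' @return List: `coefficients` (named), `risk` (a `risk_table`),
#'   `dropped` (constant columns), `fit` (the `coxph` object).
#' @export
baseline_linear_ph <- function(cohort) {
  if (sum(cohort$event) == 0) stopf("no events: Cox model undefined")
  Xall <- cbind(cohort$features, cohort$clinical)
  const <- which(apply(Xall, 2, function(x) length(unique(x)) == 1))
  if (length(const) > 0) {
    message(sprintf("baseline_linear_ph: dropping constant column(s): %s",
                    paste(colnames(Xall)[const], collapse = ", ")))
    Xall <- Xall[, -const, drop = FALSE]
  }
  if (ncol(Xall) == 0) stopf("no non-constant covariates to fit")
  df <- as.data.frame(Xall)
  df$.time <- cohort$time
  df$.event <- cohort$event
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ .,
    data = df, ties = "breslow",
    control = survival::coxph.control(iter.max = 100))
  if (!is.null(fit$info) && isTRUE(fit$fail)) {
    stopf("coxph failed to converge: %s", fit$info)
  }
  lp <- drop(Xall %*% stats::coef(fit))
  list(coefficients = stats::coef(fit),
       risk = structure(data.frame(patient_id = cohort$patient_id,
                                   risk = lp, stringsAsFactors = FALSE),
                        class = c("risk_table", "data.frame")),
       dropped = if (length(const)) colnames(cbind(cohort$features,
                                                   cohort$clinical))[const]
                 else character(0),
       fit = fit)
}

#' Serialize a trained model to structured text (JSON)
#' @param model A `vnn_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  tmp <- tempfile(fileext = ".json")
  write_vnn_spec(model$spec, tmp)
  spec_obj <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  unlink(tmp)
  obj <- list(format = "vnn_model/1",
              spec = spec_obj,
              vnn = lapply(model$vnn, function(l)
                list(W = as.vector(l$W), b = l$b)),
              root = if (!is.null(model$root))
                list(W = as.vector(model$root$W), b = model$root$b),
              head = list(W1 = as.vector(model$head$W1), b1 = model$head$b1,
                          W2 = as.vector(model$head$W2), b2 = model$head$b2),
              n_clinical = model$n_clinical,
              head_width = model$head_width,
              dropout = model$dropout,
              activation = model$activation,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path Path to the JSON file.
#' @return A `vnn_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "vnn_model/1")) stopf("not a vnn_model file")
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(obj$spec, tmp, auto_unbox = TRUE, digits = NA)
  spec <- read_vnn_spec(tmp)
  unlink(tmp)
  model <- init_model(spec, n_clinical = obj$n_clinical,
                      head_width = obj$head_width, dropout = obj$dropout,
                      activation = obj$activation, seed = obj$seed)
  for (l in seq_along(model$vnn)) {
    model$vnn[[l]]$W <- matrix(obj$vnn[[l]]$W, nrow(model$vnn[[l]]$W))
    dimnames(model$vnn[[l]]$W) <- dimnames(spec$layers[[l]]$mask)
    model$vnn[[l]]$b <- obj$vnn[[l]]$b
  }
  if (!is.null(model$root)) {
    model$root$W <- matrix(obj$root$W, nrow(model$root$W))
    model$root$b <- obj$root$b
  }
  model$head$W1 <- matrix(obj$head$W1, nrow(model$head$W1))
  model$head$b1 <- obj$head$b1
  model$head$W2 <- matrix(obj$head$W2, ncol = 1)
  model$head$b2 <- obj$head$b2
  model
}
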