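# Shapley-value attribution. The value function is interventional: the
# model is evaluated on hybrids of the explained patient and a background
# sample. Input-scope players are the input columns (genetic + clinical);
# pathway-scope players are the retained pathways, intervened on by
# clamping their hidden-layer unit activations to the background's
# activations. Exact mode enumerates coalitions (<= 15 players); sampling
# mode averages marginal contributions over seeded random permutations,
# caching coalition evaluations so repeated coalitions cost nothing.

shapley_weights <- function(p) {
  # w[s+1] = s! (p-s-1)! / p!  for coalition size s = 0..p-1
  s <- 0:(p - 1)
  exp(lgamma(s + 1) + lgamma(p - s) - lgamma(p + 1))
}

# Generic engine over a coalition value function.
# v_fun(idx) -> numeric vector (one value per explained patient),
# already averaged over the background.
shap_engine <- function(p, n, v_fun, method, n_samples, seed) {
  if (method == "exact") {
    if (p > 15) stopf("exact Shapley limited to <= 15 players (got %d)", p)
    w <- shapley_weights(p)
    nS <- bitwShiftL(1L, p)
    V <- matrix(0, nS, n)
    sizes <- integer(nS)
    for (m in seq_len(nS) - 1L) {
      idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0)
      sizes[m + 1] <- length(idx)
      V[m + 1, ] <- v_fun(idx)
    }
    phi <- matrix(0, n, p)
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      without <- which(bitwAnd(seq_len(nS) - 1L, bit) == 0)
      for (m in without) {
        phi[, j] <- phi[, j] +
          w[sizes[m] + 1] * (V[m + bit, ] - V[m, ])
      }
    }
    list(phi = phi, base = V[1, ])
  } else {
    m_perms <- max(1L, as.integer(round(n_samples / (p + 1))))
    cache <- new.env(parent = emptyenv())
    v_cached <- function(idx) {
      key <- paste0("k", paste(idx, collapse = ","))
      got <- cache[[key]]
      if (is.null(got)) {
        got <- v_fun(idx)
        cache[[key]] <- got
      }
      got
    }
    phi <- matrix(0, n, p)
    base <- v_cached(integer(0))
    perms <- with_seed(seed, replicate(m_perms, sample.int(p),
                                       simplify = FALSE))
    for (perm in perms) {
      prev <- base
      acc <- integer(0)
      for (j in perm) {
        acc <- sort(c(acc, j))
        cur <- v_cached(acc)
        phi[, j] <- phi[, j] + (cur - prev)
        prev <- cur
      }
    }
    list(phi = phi / m_perms, base = base)
  }
}

#' Shapley attributions for input features and/or hidden pathways
#'
#' @param model A `vnn_model`.
#' @param cohort A `cohort_table` of patients to explain.
#' @param background A `cohort_table` used as the interventional
#'   background (e.g. [background_cohort()]); must be non-empty.
#' @param scope `"inputs"` (genetic + clinical input columns),
#'   `"pathways"` (retained pathways, clamped at their hidden layers),
#'   or `"both"` (returns a list with both matrices).
#' @param method `"exact"` coalition enumeration (<= 15 players) or
#'   `"sampling"` (seeded permutation sampling).
#' @param n_samples Sampling budget: roughly the number of model
#'   evaluations per patient; the number of permutations used is
#'   `n_samples / (n_players + 1)`.
#' @param seed Integer seed for sampling mode.
#' @return A `shap_matrix`: `values` (patients x players), `base_value`
#'   (scalar for input scope; per-patient for pathway scope, where the
#'   patient's own gene values still travel the skip-through channels),
#'   `node_names`, `scope`. For `scope = "both"`, a named list of two
#'   `shap_matrix` objects.
#' @export
shap_values <- function(model, cohort, background,
                        scope = c("inputs", "pathways", "both"),
                        method = c("sampling", "exact"),
                        n_samples = 2048L, seed = 1L) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  if (n_patients(background) == 0) stopf("background must be non-empty")
  if (scope == "both") {
    return(list(
      inputs = shap_values(model, cohort, background, "inputs", method,
                           n_samples, seed),
      pathways = shap_values(model, cohort, background, "pathways", method,
                             n_samples, seed)))
  }
  inp <- cohort_inputs(model, cohort)
  bg <- cohort_inputs(model, background)
  n <- n_patients(cohort)
  nb <- n_patients(background)

  if (scope == "inputs") {
    XC <- cbind(inp$X, inp$C)
    XCbg <- cbind(bg$X, bg$C)
    p <- ncol(XC)
    pg <- ncol(inp$X)
    v_fun <- function(idx) {
      acc <- numeric(n)
      for (b in seq_len(nb)) {
        H <- matrix(XCbg[b, ], n, p, byrow = TRUE)
        if (length(idx) > 0) H[, idx] <- XC[, idx, drop = FALSE]
        acc <- acc + nn_forward(model, H[, seq_len(pg), drop = FALSE],
                                H[, pg + seq_len(p - pg), drop = FALSE])$risk
      }
      acc / nb
    }
    node_names <- colnames(XC)
  } else {
    players <- names(model$spec$layer_of)
    p <- length(players)
    # unit activations of every background row, per layer
    bg_acts <- lapply(seq_len(nb), function(b) {
      fw <- nn_forward(model, bg$X[b, , drop = FALSE],
                       bg$C[b, , drop = FALSE], keep = TRUE)
      lapply(fw$acts$vnn, function(st) {
        stats::setNames(drop(st$Hout), colnames(st$Hout) %||%
                          model$spec$layers[[1]]$out_names)
      })
    })
    unit_names <- lapply(model$spec$layers, `[[`, "out_names")
    units_of <- function(pw) {
      if (model$spec$node_width == 1) paste0("p:", pw) else
        paste0("p:", rep(pw, each = model$spec$node_width), "#",
               seq_len(model$spec$node_width))
    }
    v_fun <- function(idx) {
      off <- setdiff(players, players[idx])
      if (length(off) == 0) {
        return(nn_forward(model, inp$X, inp$C)$risk)
      }
      off_units <- units_of(off)
      acc <- numeric(n)
      for (b in seq_len(nb)) {
        acts <- lapply(seq_along(unit_names), function(l) {
          sub <- bg_acts[[b]][[l]]
          sub[intersect(names(sub), off_units)]
        })
        acc <- acc + nn_forward(model, inp$X, inp$C,
                                clamp = list(off = off, acts = acts))$risk
      }
      acc / nb
    }
    node_names <- players
  }
  res <- shap_engine(p, n, v_fun, method, n_samples, seed)
  colnames(res$phi) <- node_names
  rownames(res$phi) <- cohort$patient_id
  base <- res$base
  if (scope == "inputs") base <- base[1]  # identical across patients
  structure(list(values = res$phi,
                 base_value = base,
                 node_names = node_names,
                 scope = scope,
                 method = method),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("shap_matrix (%s, %s): %d patients x %d nodes\n",
              x$scope, x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Background cohorts for Shapley attribution
#'
#' Either a seeded subsample of the cohort (default, `type = "sample"`)
#' or the single all-zeros alteration profile (`type = "zeros"`, clinical
#' also zero).
#'
#' @param cohort A `cohort_table`.
#' @param n_background Number of background patients (sample type).
#' @param type `"sample"` or `"zeros"`.
#' @param seed Integer seed for the subsample.
#' @return A `cohort_table`.
#' @export
background_cohort <- function(cohort, n_background = 100L,
                              type = c("sample", "zeros"), seed = 1L) {
  type <- match.arg(type)
  if (type == "zeros") {
    return(cohort_table(
      "background_zero",
      matrix(0, 1, ncol(cohort$features),
             dimnames = list(NULL, colnames(cohort$features))),
      matrix(0, 1, ncol(cohort$clinical),
             dimnames = list(NULL, colnames(cohort$clinical))),
      time = 1, event = 0L))
  }
  n <- n_patients(cohort)
  idx <- if (n <= n_background) seq_len(n) else
    with_seed(seed, sort(sample.int(n, n_background)))
  subset_cohort(cohort, idx)
}

#' Feature impact: mean SHAP over altered cases only
#'
#' `Impact_j = (1/N_j) * sum over {i : f_ij = 1} of s_ij`, where `N_j`
#' counts the patients carrying alteration `j`. Averaging over carriers
#' only keeps low-frequency alterations visible. Never-altered features
#' get impact 0 with `flagged = TRUE` (the mean is undefined).
#'
#' @param shap A `shap_matrix` with input scope.
#' @param cohort The `cohort_table` the SHAP values were computed on
#'   (same patients, same order).
#' @return data.frame `impact_table`: `feature`, `impact`, `n_altered`,
#'   `flagged`, sorted by decreasing `|impact|`.
#' @export
feature_impact <- function(shap, cohort) {
  if (inherits(shap, "shap_matrix")) {
    if (!identical(rownames(shap$values), cohort$patient_id)) {
      stopf("shap rows do not align with the cohort's patients")
    }
    S <- shap$values
  } else {
    S <- as.matrix(shap)
    if (nrow(S) != n_patients(cohort)) stopf("shap rows != cohort patients")
  }
  feats <- intersect(colnames(S), cohort$feature_names)
  if (length(feats) == 0) stopf("no genetic feature columns in the shap matrix")
  out <- data.frame(feature = feats,
                    impact = NA_real_, n_altered = NA_integer_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(feats)) {
    f <- feats[k]
    carriers <- cohort$features[, f] == 1
    out$n_altered[k] <- sum(carriers)
    if (out$n_altered[k] == 0) {
      out$impact[k] <- 0
      out$flagged[k] <- TRUE
    } else {
      out$impact[k] <- mean(S[carriers, f])
    }
  }
  out <- out[order(-abs(out$impact)), ]
  rownames(out) <- NULL
  class(out) <- c("impact_table", "data.frame")
  out
}
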