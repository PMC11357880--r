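# Impact-ranked backward feature elimination: repeatedly train on the
# current gene panel, attribute with SHAP, drop the least impactful
# genes (smallest |impact|), rebuild the architecture on the reduced
# panel and re-estimate held-out performance.

#' Impact-ranked backward feature elimination
#'
#' At each round: build the pathway architecture on the current gene
#' panel, train one model on the full cohort, compute input-scope SHAP
#' values and the altered-cases impact statistic, record the mean
#' held-out C-index from k-fold cross-validation at this panel size,
#' then drop the `step` genes with the smallest `|impact|` (both
#' harmful and protective alterations matter, so the magnitude ranks).
#' Stops cleanly when `step` or fewer genes remain.
#'
#' @param cohort A `cohort_table`.
#' @param gene_sets A `gene_set_collection`.
#' @param hierarchy A `hierarchy_edges` data.frame.
#' @param step Genes removed per round (>= 1).
#' @param hp [hyperparams()] for the per-round training runs.
#' @param k_folds Folds for the per-round CV estimate.
#' @param min_features Stop before the panel would drop below this size.
#' @param background_type,n_background,n_samples SHAP settings; the
#'   all-zeros background with permutation sampling keeps rounds cheap.
#' @param head_width,dropout,activation Model settings.
#' @param seed Master seed (per-round seeds derived from it).
#' @return An `elimination_curve` list: `curve` (data.frame of
#'   `n_features`, `mean_cv_cindex`), `rankings` (per-round
#'   `impact_table`s), `eliminated` (features dropped per round, in
#'   order), `final_features`.
#' @export
rank_and_eliminate <- function(cohort, gene_sets, hierarchy, step = 5L,
                               hp = hyperparams(), k_folds = 5L,
                               min_features = 1L,
                               background_type = "zeros",
                               n_background = 50L, n_samples = 1024L,
                               head_width = 64L, dropout = 0.2,
                               activation = "tanh", seed = 1L) {
  stopifnot(step >= 1)
  genes <- cohort$feature_names
  rounds <- list()
  eliminated <- list()
  curve <- data.frame(n_features = integer(0), mean_cv_cindex = numeric(0))
  round_i <- 0
  seeds <- derive_seeds(seed, 1000)
  cur <- cohort
  while (length(genes) >= max(min_features, 1)) {
    round_i <- round_i + 1
    s <- seeds[(round_i - 1) * 3 + 1:3]
    spec <- build_vnn_spec(gene_sets, hierarchy, genes)
    mdl <- init_model(spec, ncol(cur$clinical), head_width = head_width,
                      dropout = dropout, activation = activation,
                      seed = s[1])
    hp_r <- hp
    hp_r$seed <- s[1]
    hp_r$batch_size <- min(hp$batch_size, n_patients(cur))
    fit <- train_model(mdl, cur, hp_r)
    bg <- background_cohort(cur, n_background, type = background_type,
                            seed = s[2])
    sh <- shap_values(fit$model, cur, bg, scope = "inputs",
                      method = if (length(genes) + ncol(cur$clinical) <= 12)
                        "exact" else "sampling",
                      n_samples = n_samples, seed = s[2])
    imp <- feature_impact(sh, cur)
    cv <- cross_validate(cur, spec, grid = list(hp_r), k = k_folds,
                         seed = s[3], head_width = head_width,
                         dropout = dropout, activation = activation)
    curve <- rbind(curve, data.frame(n_features = length(genes),
                                     mean_cv_cindex = mean(cv$fold_scores)))
    rounds[[round_i]] <- imp
    if (length(genes) <= step || length(genes) - step < min_features) break
    drop_feats <- utils::tail(imp$feature, step)  # smallest |impact|
    eliminated[[round_i]] <- drop_feats
    genes <- setdiff(genes, drop_feats)
    keep_idx <- match(genes, colnames(cur$features))
    cur <- cohort_table(cur$patient_id,
                        cur$features[, keep_idx, drop = FALSE],
                        cur$clinical, cur$time, cur$event)
  }
  structure(list(curve = curve, rankings = rounds,
                 eliminated = eliminated, final_features = genes),
            class = "elimination_curve")
}

#' @export
print.elimination_curve <- function(x, ...) {
  cat("elimination_curve:\n")
  print(x$curve)
  invisible(x)
}
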