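# Genetic prognostic index (GPI), three-level risk stratification,
# pairwise alteration interaction analysis (co-occurrence / mutual
# exclusivity), UpSet-style intersection counts, and subtype assignment.

#' Genetic prognostic index score
#'
#' `score_i = sum over j in F_key of f_ij * Impact_j`: a per-patient
#' weighted sum of key alteration indicators by their impacts.
#'
#' @param cohort A `cohort_table`.
#' @param impact An `impact_table` (from [feature_impact()]) or a named
#'   numeric vector of impacts.
#' @param f_key Key feature names (subset of both the impact table and
#'   the cohort's features).
#' @return Named numeric vector of scores (one per patient).
#' @export
gpi_score <- function(cohort, impact, f_key) {
  imp <- if (is.data.frame(impact)) {
    stats::setNames(impact$impact, impact$feature)
  } else {
    impact
  }
  missing_cohort <- setdiff(f_key, cohort$feature_names)
  if (length(missing_cohort) > 0) {
    stopf("key feature(s) absent from cohort: %s",
          paste(missing_cohort, collapse = ", "))
  }
  missing_imp <- setdiff(f_key, names(imp))
  if (length(missing_imp) > 0) {
    stopf("key feature(s) without an impact value: %s",
          paste(missing_imp, collapse = ", "))
  }
  scores <- drop(cohort$features[, f_key, drop = FALSE] %*% imp[f_key])
  stats::setNames(as.numeric(scores), cohort$patient_id)
}

#' Three-level risk stratification of GPI scores
#'
#' `score <= t1` -> level I; `t1 < score <= t2` -> level II;
#' `score > t2` -> level III. Boundary scores fall to the lower level.
#'
#' @param scores Numeric GPI scores.
#' @param t1,t2 Thresholds with `t1 < t2`.
#' @return Factor with levels `I`, `II`, `III`.
#' @export
assign_levels <- function(scores, t1, t2) {
  if (!(t1 < t2)) stopf("need t1 < t2 (got %g >= %g)", t1, t2)
  lev <- ifelse(scores <= t1, "I", ifelse(scores <= t2, "II", "III"))
  factor(lev, levels = c("I", "II", "III"))
}

#' Search stratification thresholds by survival separation
#'
#' Evaluates every ordered grid pair `(t1 < t2)` whose three resulting
#' levels each hold at least `min_group` patients, and picks the pair
#' minimizing the worst (largest) of the three pairwise log-rank
#' p-values. Ties break toward more balanced group sizes (smaller
#' standard deviation of the three counts), then the lexicographically
#' smaller `(t1, t2)`.
#'
#' @param scores Numeric GPI scores.
#' @param time,event Survival data aligned with `scores`.
#' @param grid Candidate threshold values (>= 2 distinct).
#' @param min_group Minimum patients per level (default 5).
#' @return List: `t1`, `t2`, `worst_p`, `diagnostics` (all admissible
#'   pairs with their worst p and group sizes).
#' @export
optimize_thresholds <- function(scores, time, event, grid, min_group = 5L) {
  grid <- sort(unique(grid))
  if (length(grid) < 2) stopf("grid needs at least 2 distinct values")
  rows <- list()
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (j <= i) next
      t1 <- grid[i]; t2 <- grid[j]
      lev <- assign_levels(scores, t1, t2)
      cnt <- table(lev)
      if (any(cnt < min_group)) next
      ps <- vapply(list(c("I", "II"), c("I", "III"), c("II", "III")),
                   function(pair) {
                     sel <- lev %in% pair
                     logrank_test(time[sel], event[sel],
                                  droplevels(lev[sel]))$p_value
                   }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        t1 = t1, t2 = t2, worst_p = max(ps),
        n_I = cnt[["I"]], n_II = cnt[["II"]], n_III = cnt[["III"]],
        balance = stats::sd(as.numeric(cnt)))
    }
  }
  if (length(rows) == 0) {
    stopf("no admissible threshold pair: every candidate leaves a level with fewer than %d patients",
          min_group)
  }
  diag <- do.call(rbind, rows)
  ord <- order(diag$worst_p, diag$balance, diag$t1, diag$t2)
  best <- diag[ord[1], ]
  list(t1 = best$t1, t2 = best$t2, worst_p = best$worst_p,
       diagnostics = diag)
}

#' Pairwise co-occurrence / mutual-exclusivity analysis
#'
#' For every unordered feature pair, the 2x2 contingency table of joint
#' presence/absence is tested with a two-sided Fisher exact test;
#' Benjamini-Hochberg FDR across all tested pairs. A pair is labelled
#' `co-occurrence` when `q < alpha` and the odds ratio exceeds 1,
#' `exclusivity` when `q < alpha` and the odds ratio is below 1, and
#' `none` otherwise. The sample odds ratio `(a*d)/(b*c)` is reported
#' with the Inf/0 convention for degenerate cells alongside a
#' Haldane-corrected version (0.5 added to every cell) for plotting.
#'
#' @param cohort A `cohort_table`.
#' @param features Feature names to test (default: all genetic
#'   features); constant columns are excluded with a notice.
#' @param alpha FDR level for labelling (default 0.05).
#' @return data.frame `interaction_table`: `feature_a`, `feature_b`,
#'   `n11`, `n10`, `n01`, `n00`, `odds_ratio`, `odds_ratio_haldane`,
#'   `p_value`, `q_value`, `label`.
#' @export
pairwise_interactions <- function(cohort, features = NULL, alpha = 0.05) {
  features <- features %||% cohort$feature_names
  miss <- setdiff(features, cohort$feature_names)
  if (length(miss) > 0) stopf("unknown feature(s): %s",
                              paste(miss, collapse = ", "))
  X <- cohort$features[, features, drop = FALSE]
  const <- apply(X, 2, function(x) length(unique(x)) == 1)
  if (any(const)) {
    message(sprintf("pairwise_interactions: excluding constant feature(s): %s",
                    paste(features[const], collapse = ", ")))
    features <- features[!const]
    X <- X[, features, drop = FALSE]
  }
  if (length(features) < 2) stopf("need at least 2 non-constant features")
  pairs <- utils::combn(features, 2)
  res <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    fa <- pairs[1, k]; fb <- pairs[2, k]
    a <- sum(X[, fa] == 1 & X[, fb] == 1)
    b <- sum(X[, fa] == 1 & X[, fb] == 0)
    c_ <- sum(X[, fa] == 0 & X[, fb] == 1)
    d <- sum(X[, fa] == 0 & X[, fb] == 0)
    p <- stats::fisher.test(matrix(c(a, c_, b, d), 2), alternative = "two.sided")$p.value
    or <- if (b * c_ == 0) {
      if (a * d == 0) NaN else Inf
    } else {
      (a * d) / (b * c_)
    }
    or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    res[[k]] <- data.frame(feature_a = fa, feature_b = fb,
                           n11 = a, n10 = b, n01 = c_, n00 = d,
                           odds_ratio = or, odds_ratio_haldane = or_h,
                           p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  effective_or <- ifelse(is.nan(out$odds_ratio), out$odds_ratio_haldane,
                         out$odds_ratio)
  out$label <- ifelse(out$q_value < alpha & effective_or > 1, "co-occurrence",
                      ifelse(out$q_value < alpha & effective_or < 1,
                             "exclusivity", "none"))
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Exclusive intersection counts (UpSet semantics)
#'
#' Counts patients by their exact presence/absence pattern over the
#' listed features; zero-count patterns are omitted. Counts partition
#' the cohort.
#'
#' @param cohort A `cohort_table`.
#' @param features Feature names (non-empty).
#' @return data.frame: `pattern` (e.g. `"A+B"` or `"(none)"`), one
#'   indicator column per feature, `count`; sorted by decreasing count.
#' @export
intersection_counts <- function(cohort, features) {
  stopifnot(length(features) >= 1)
  miss <- setdiff(features, cohort$feature_names)
  if (length(miss) > 0) stopf("unknown feature(s): %s",
                              paste(miss, collapse = ", "))
  X <- cohort$features[, features, drop = FALSE]
  key <- apply(X, 1, paste, collapse = "")
  tab <- table(key)
  rows <- lapply(names(tab), function(k) {
    bits <- as.integer(strsplit(k, "")[[1]])
    present <- features[bits == 1]
    df <- as.data.frame(as.list(stats::setNames(bits, features)))
    df$pattern <- if (length(present) == 0) "(none)" else
      paste(present, collapse = "+")
    df$count <- as.integer(tab[[k]])
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$count, out$pattern), c("pattern", features, "count")]
  rownames(out) <- NULL
  out
}

#' Marker-based subtype assignment
#'
#' A patient carrying any high-risk marker is `H1`; any low-risk marker,
#' `L1`; both kinds, the explicit label `both`; neither, `unclassified`.
#'
#' @param cohort A `cohort_table`.
#' @param h1_markers,l1_markers Disjoint marker feature sets present in
#'   the cohort.
#' @return data.frame: `patient_id`, `subtype`
#'   (factor H1/L1/both/unclassified).
#' @export
assign_subtypes <- function(cohort, h1_markers, l1_markers) {
  if (length(intersect(h1_markers, l1_markers)) > 0) {
    stopf("marker sets overlap: %s",
          paste(intersect(h1_markers, l1_markers), collapse = ", "))
  }
  miss <- setdiff(c(h1_markers, l1_markers), cohort$feature_names)
  if (length(miss) > 0) stopf("marker(s) absent from cohort: %s",
                              paste(miss, collapse = ", "))
  h <- rowSums(cohort$features[, h1_markers, drop = FALSE]) > 0
  l <- rowSums(cohort$features[, l1_markers, drop = FALSE]) > 0
  sub <- ifelse(h & l, "both", ifelse(h, "H1", ifelse(l, "L1", "unclassified")))
  data.frame(patient_id = cohort$patient_id,
             subtype = factor(sub, levels = c("H1", "L1", "both",
                                              "unclassified")),
             stringsAsFactors = FALSE)
}

#' Sub-subtype assignment by per-patient SHAP rank of an anchor feature
#'
#' Among patients carrying the anchor alteration, rank all genetic
#' features by `|SHAP|` (competition ranking: ties share the better
#' rank). If the anchor ranks within the top `top_k`, the patient is
#' assigned sub-subtype `II` (anchor-dominant, the worse-prognosis
#' convention); otherwise `I`.
#'
#' @param shap An input-scope `shap_matrix`.
#' @param cohort The matching `cohort_table`.
#' @param anchor_feature The anchor alteration name (e.g. a MYD88 hotspot
#'   indicator).
#' @param top_k Rank cutoff (default 5).
#' @return data.frame: `patient_id`, `anchor_rank`, `sub_subtype`
#'   (factor I/II/NA); rows only for anchor-positive patients.
#' @export
sub_subtype_by_shap_rank <- function(shap, cohort, anchor_feature,
                                     top_k = 5L) {
  S <- shap$values
  feats <- intersect(colnames(S), cohort$feature_names)
  if (!anchor_feature %in% feats) {
    stopf("anchor feature '%s' not present in the SHAP matrix/cohort",
          anchor_feature)
  }
  carriers <- which(cohort$features[, anchor_feature] == 1)
  if (length(carriers) == 0) {
    return(data.frame(patient_id = character(0), anchor_rank = integer(0),
                      sub_subtype = factor(character(0),
                                           levels = c("I", "II"))))
  }
  ranks <- vapply(carriers, function(i) {
    v <- abs(S[i, feats])
    as.integer(rank(-v, ties.method = "min")[[anchor_feature]])
  }, integer(1))
  data.frame(patient_id = cohort$patient_id[carriers],
             anchor_rank = ranks,
             sub_subtype = factor(ifelse(ranks <= top_k, "II", "I"),
                                  levels = c("I", "II")),
             stringsAsFactors = FALSE)
}
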