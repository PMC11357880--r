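test_that("exact Shapley attributions satisfy additivity and match naive enumeration", {
  fx <- toy_trained_model(n = 12, n_genes = 4, seed = 19)
  bg <- background_cohort(fx$cohort, 2, seed = 3)
  ex <- shap_values(fx$model, fx$cohort, bg, scope = "inputs",
                    method = "exact")
  rk <- predict_risk(fx$model, fx$cohort)$risk
  expect_lt(max(abs(ex$base_value + rowSums(ex$values) - rk)), 1e-3)
  # independent subset-enumeration oracle, first three patients
  for (i in 1:3) {
    want <- oracle_shapley_inputs(fx$model, fx$cohort, bg, i)
    expect_equal(ex$values[i, names(want)], want, tolerance = 1e-10)
  }
  expect_error(shap_values(fx$model, fx$cohort,
                           background_cohort(fx$cohort, 0, seed = 1)),
               "non-empty")
})

test_that("sampling attributions converge to the exact values", {
  fx <- toy_trained_model(n = 10, n_genes = 8, seed = 27)
  bg <- background_cohort(fx$cohort, 2, seed = 5)
  ex <- shap_values(fx$model, fx$cohort, bg, scope = "inputs",
                    method = "exact")
  sa <- shap_values(fx$model, fx$cohort, bg, scope = "inputs",
                    method = "sampling", n_samples = 2^14, seed = 8)
  expect_lt(max(abs(ex$values - sa$values)), 0.02)
  sa2 <- shap_values(fx$model, fx$cohort, bg, scope = "inputs",
                     method = "sampling", n_samples = 2^14, seed = 8)
  expect_identical(sa$values, sa2$values)  # seed-deterministic
})

test_that("a linear network recovers the closed-form attribution w_j * x_ij", {
  fx <- toy_trained_model(n = 15, n_genes = 5, seed = 33,
                          activation = "identity")
  co <- fx$cohort
  bg0 <- background_cohort(co, type = "zeros")
  ex <- shap_values(fx$model, co, bg0, scope = "inputs", method = "exact")
  zero <- co; zero$features[] <- 0
  f0 <- predict_risk(fx$model, zero)$risk[1]
  w <- vapply(seq_len(ncol(co$features)), function(j) {
    one <- zero; one$features[1, j] <- 1
    predict_risk(fx$model, one)$risk[1] - f0
  }, numeric(1))
  expect_equal(unname(ex$values[, colnames(co$features)]),
               unname(sweep(co$features, 2, w, "*")), tolerance = 1e-10)
})

test_that("pathway-scope attributions are additive around the clamped baseline", {
  fx <- toy_trained_model(n = 10, n_genes = 6, seed = 41)
  bg <- background_cohort(fx$cohort, 3, seed = 2)
  pw <- shap_values(fx$model, fx$cohort, bg, scope = "pathways",
                    method = "exact")
  rk <- predict_risk(fx$model, fx$cohort)$risk
  expect_lt(max(abs(pw$base_value + rowSums(pw$values) - rk)), 1e-3)
  expect_setequal(colnames(pw$values), names(fx$model$spec$layer_of))
})

test_that("features with no path to the output get zero attribution", {
  fx <- toy_trained_model(n = 10, n_genes = 5, seed = 51)
  m <- fx$model
  # disconnect the first gene: zero every trainable weight in its rows
  g <- paste0("g:", colnames(fx$cohort$features)[1])
  for (l in seq_along(m$vnn)) {
    ls <- m$spec$layers[[l]]
    if (g %in% rownames(ls$mask)) {
      m$vnn[[l]]$W[g, ls$trainable[g, ]] <- 0
    }
  }
  bg <- background_cohort(fx$cohort, 2, seed = 1)
  ex <- shap_values(m, fx$cohort, bg, scope = "inputs", method = "exact")
  expect_equal(max(abs(ex$values[, colnames(fx$cohort$features)[1]])), 0)
})

test_that("feature impact equals the altered-cases mean and flags never-altered", {
  # direct formula: s = (0.2, -0.1, 0.4), f = (1, 0, 1) -> impact 0.3
  co <- cohort_table(c("a", "b", "c"),
                     matrix(c(1, 0, 1, 0, 0, 0), 3,
                            dimnames = list(NULL, c("F1", "F2"))),
                     NULL, time = c(1, 2, 3), event = c(1L, 1L, 0L))
  S <- matrix(c(0.2, -0.1, 0.4, 1, 2, 3), 3,
              dimnames = list(c("a", "b", "c"), c("F1", "F2")))
  imp <- feature_impact(S, co)
  expect_equal(imp$impact[imp$feature == "F1"], 0.3)
  expect_equal(imp$n_altered[imp$feature == "F1"], 2L)
  f2 <- imp[imp$feature == "F2", ]
  expect_equal(f2$impact, 0)
  expect_true(f2$flagged)
  # random instance vs masked-mean brute force
  withr::with_seed(61, {
    n <- 50; p <- 10
    X <- matrix(rbinom(n * p, 1, 0.3), n,
                dimnames = list(NULL, paste0("G", 1:p)))
    X[, 1] <- 1  # ensure at least one fully-altered column
    coh <- cohort_table(paste0("p", 1:n), X, NULL,
                        time = rexp(n) + 0.1, event = rep(1L, n))
    Sv <- matrix(rnorm(n * p), n, dimnames = list(coh$patient_id,
                                                  colnames(X)))
    got <- feature_impact(Sv, coh)
    for (j in colnames(X)) {
      carriers <- X[, j] == 1
      want <- if (any(carriers)) sum(Sv[carriers, j]) / sum(carriers) else 0
      expect_equal(got$impact[got$feature == j], want, tolerance = 1e-12)
    }
  })
})

test_that("feature impact is equivariant under patient permutation", {
  fx <- toy_trained_model(n = 14, n_genes = 5, seed = 71)
  bg <- background_cohort(fx$cohort, type = "zeros")
  ex <- shap_values(fx$model, fx$cohort, bg, scope = "inputs",
                    method = "exact")
  imp <- feature_impact(ex, fx$cohort)
  perm <- withr::with_seed(2, sample(n_patients(fx$cohort)))
  co_p <- vnnsurv:::subset_cohort(fx$cohort, perm)
  S_p <- ex$values[perm, , drop = FALSE]
  imp_p <- feature_impact(S_p, co_p)
  expect_equal(imp[order(imp$feature), c("impact", "n_altered")],
               imp_p[order(imp_p$feature), c("impact", "n_altered")],
               ignore_attr = TRUE)
})

test_that("sankey widths are proportional and conserved before pruning", {
  fx <- toy_trained_model(n = 12, n_genes = 6, seed = 81)
  bg <- background_cohort(fx$cohort, 2, seed = 4)
  exi <- shap_values(fx$model, fx$cohort, bg, scope = "inputs",
                     method = "exact")
  exp_ <- shap_values(fx$model, fx$cohort, bg, scope = "pathways",
                      method = "exact")
  sk <- build_sankey(fx$model$spec, exp_, exi, prune_fraction = 0)
  # conservation: incoming edge widths sum to the target's width
  for (t in unique(sk$edges$target)) {
    expect_equal(sum(sk$edges$width[sk$edges$target == t]),
                 sk$nodes$width[sk$nodes$name == t], tolerance = 1e-9)
  }
  # direct two-source proportionality on a constructed case
  spec <- build_vnn_spec(
    gene_set_collection(list(T1 = c("A", "B"))),
    hierarchy_edges(character(0), character(0)), c("A", "B"))
  shap_in <- structure(list(values = matrix(c(0.3, -0.3, 0.1, 0.1), 2,
                                            dimnames = list(NULL, c("A", "B"))),
                            base_value = 0), class = "shap_matrix")
  shap_pw <- structure(list(values = matrix(c(0.8, -0.8), 2,
                                            dimnames = list(NULL, "T1")),
                            base_value = 0), class = "shap_matrix")
  sk2 <- build_sankey(spec, shap_pw, shap_in, prune_fraction = 0)
  expect_equal(sort(sk2$edges$width), c(0.2, 0.6))
  # pruning drops the smallest edges
  sk3 <- build_sankey(fx$model$spec, exp_, exi, prune_fraction = 0.5)
  expect_lt(nrow(sk3$edges), nrow(sk$edges))
  expect_gte(min(sk3$edges$width),
             stats::quantile(sk$edges$width, 0.5, names = FALSE) - 1e-12)
  # round-trip
  f <- withr::local_tempfile()
  write_results(sk, f)
  back <- read_results(f)
  expect_s3_class(back, "sankey_graph")
  expect_equal(back$edges$width, sk$edges$width, tolerance = 1e-10)
  expect_equal(back$nodes$width, sk$nodes$width, tolerance = 1e-10)
})
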