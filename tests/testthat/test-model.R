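make_spec_cohort <- function(n = 40, seed = 5) {
  hier <- simulate_hierarchy(6, 8, 3, seed = seed)
  genes <- sort(unique(unlist(hier$gene_sets)))
  truth <- ground_truth(stats::setNames(c(log(2), rep(0, length(genes) - 1)),
                                        genes),
                        seed = seed)
  sim <- simulate_cohort(n, stats::setNames(rep(0.4, length(genes)), genes),
                         truth)
  list(spec = build_vnn_spec(hier$gene_sets, hier$hierarchy, genes),
       cohort = sim$cohort)
}

test_that("initialization is seed-deterministic and validates dropout", {
  sc <- make_spec_cohort()
  m1 <- init_model(sc$spec, 3, seed = 11)
  m2 <- init_model(sc$spec, 3, seed = 11)
  expect_identical(m1, m2)
  m3 <- init_model(sc$spec, 3, seed = 12)
  expect_false(identical(m1$head$W1, m3$head$W1))
  expect_error(init_model(sc$spec, 3, dropout = 1.0), "dropout")
  # n_clinical = 0 -> head input equals root width
  m0 <- init_model(sc$spec, 0, seed = 1)
  expect_equal(nrow(m0$head$W1), sc$spec$root_width)
})

test_that("forward is deterministic in eval mode and honors the masks", {
  sc <- make_spec_cohort()
  m <- init_model(sc$spec, 3, seed = 2)
  r1 <- predict_risk(m, sc$cohort)
  r2 <- predict_risk(m, sc$cohort)
  expect_identical(r1, r2)
  # zero weights -> zero risk (biases start at zero)
  mz <- m
  for (l in seq_along(mz$vnn)) {
    mz$vnn[[l]]$W[sc$spec$layers[[l]]$trainable] <- 0
  }
  mz$head$W1[] <- 0; mz$head$W2[] <- 0
  expect_equal(predict_risk(mz, sc$cohort)$risk,
               rep(0, n_patients(sc$cohort)))
  # perturbing a masked-out slot leaves outputs bit-identical
  mp <- m
  off <- which(sc$spec$layers[[1]]$mask == 0, arr.ind = TRUE)
  mp$vnn[[1]]$W[off[1, 1], off[1, 2]] <- 99
  expect_identical(predict_risk(mp, sc$cohort)$risk, r1$risk)
  # feature-name mismatch is rejected with the difference listed
  bad <- sc$cohort
  colnames(bad$features)[1] <- "WRONG"
  bad$feature_names <- colnames(bad$features)
  expect_error(predict_risk(m, bad), "WRONG")
})

test_that("cox_loss matches closed forms and the enumeration oracle", {
  # single event patient: r - log(exp(r)) = 0
  expect_equal(cox_loss(3.7, time = 5, event = 1), 0)
  # two patients, both events, equal risks: log 2
  expect_equal(cox_loss(c(0, 0), time = c(1, 2), event = c(1, 1)), log(2),
               tolerance = 1e-12)
  expect_error(cox_loss(c(1, 2), c(1, 2), c(0, 0)), "without events")
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- sample(2:20, 1)
      r <- rnorm(n, sd = 2)
      tt <- sample(1:8, n, replace = TRUE)  # heavy ties
      ev <- rbinom(n, 1, 0.6); ev[sample(n, 1)] <- 1
      expect_equal(cox_loss(r, tt, ev), oracle_cox_loss(r, tt, ev),
                   tolerance = 1e-10)
    }
  })
})

test_that("analytic cox gradient matches central finite differences", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- sample(3:20, 1)
      r <- rnorm(n)
      tt <- rexp(n) + 0.01
      ev <- rbinom(n, 1, 0.5); ev[sample(n, 1)] <- 1
      g <- cox_loss_grad(r, tt, ev)
      eps <- 1e-6
      gn <- vapply(seq_len(n), function(k) {
        rp <- r; rp[k] <- rp[k] + eps
        rm <- r; rm[k] <- rm[k] - eps
        (cox_loss(rp, tt, ev) - cox_loss(rm, tt, ev)) / (2 * eps)
      }, numeric(1))
      expect_equal(g, gn, tolerance = 1e-5)
    }
  })
})

test_that("training respects masks, reduces loss, and is seed-stable", {
  sc <- make_spec_cohort(n = 120, seed = 9)
  m <- init_model(sc$spec, 3, head_width = 8, seed = 3)
  # epochs = 0 returns the input parameters untouched
  f0 <- train_model(m, sc$cohort, hyperparams(epochs = 0))
  expect_identical(f0$model$vnn, m$vnn)
  fit <- train_model(m, sc$cohort, hyperparams(epochs = 15, seed = 4))
  expect_true(all(diff(fit$history[1:10]) < 0))
  # masked positions exactly zero after training
  for (l in seq_along(fit$model$vnn)) {
    expect_equal(max(abs(fit$model$vnn[[l]]$W[sc$spec$layers[[l]]$mask == 0])),
                 0)
  }
  fit2 <- train_model(m, sc$cohort, hyperparams(epochs = 15, seed = 4))
  expect_identical(fit$model, fit2$model)
})

test_that("loss and C-index are invariant under patient permutation", {
  sc <- make_spec_cohort(n = 30, seed = 12)
  co <- sc$cohort
  r <- withr::with_seed(1, rnorm(n_patients(co)))
  perm <- withr::with_seed(2, sample(n_patients(co)))
  expect_equal(cox_loss(r, co$time, co$event),
               cox_loss(r[perm], co$time[perm], co$event[perm]),
               tolerance = 1e-12)
  expect_equal(c_index(r, co$time, co$event)$value,
               c_index(r[perm], co$time[perm], co$event[perm])$value)
})

test_that("cross-validation is stratified, seeded, and reports per-fold scores", {
  sc <- make_spec_cohort(n = 50, seed = 21)
  cv <- cross_validate(sc$cohort, sc$spec,
                       grid = list(hyperparams(epochs = 3)), k = 2, seed = 5,
                       head_width = 4)
  expect_length(cv$fold_scores, 2)
  expect_true(all(cv$fold_scores >= 0 & cv$fold_scores <= 1))
  cv2 <- cross_validate(sc$cohort, sc$spec,
                        grid = list(hyperparams(epochs = 3)), k = 2, seed = 5,
                        head_width = 4)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$fold_scores, cv2$fold_scores)
  # every fold holds events
  expect_true(all(tapply(sc$cohort$event, cv$folds, sum) > 0))
})

test_that("dense baseline matches widths and exceeds the masked parameter count", {
  sc <- make_spec_cohort()
  dense <- dense_spec_like(sc$spec)
  for (l in seq_along(dense$layers)) {
    expect_identical(dim(dense$layers[[l]]$mask),
                     dim(sc$spec$layers[[l]]$mask))
    expect_gte(sum(dense$layers[[l]]$trainable),
               sum(sc$spec$layers[[l]]$trainable))
  }
  m1 <- init_model(dense, 3, seed = 6)
  m2 <- init_model(dense, 3, seed = 6)
  expect_identical(m1, m2)
})

test_that("linear PH baseline recovers a planted log-2 hazard ratio", {
  genes <- "G1"
  truth <- ground_truth(c(G1 = log(2)), baseline_hazard = 1 / 1000,
                        censor_rate_target = 0.25, seed = 77)
  sim <- simulate_cohort(2000, c(G1 = 0.5), truth, clinical_freqs = NULL)
  fit <- baseline_linear_ph(sim$cohort)
  expect_gt(fit$coefficients[["G1"]], 0.55)
  expect_lt(fit$coefficients[["G1"]], 0.85)
  # risk ordering equals the coefficient-weighted feature sum
  expect_equal(fit$risk$risk,
               unname(drop(sim$cohort$features %*% fit$coefficients)),
               tolerance = 1e-12)
  # all-censored cohort is rejected
  allc <- sim$cohort
  allc$event[] <- 0L
  expect_error(baseline_linear_ph(allc), "no events")
})

test_that("models round-trip through JSON serialization", {
  sc <- make_spec_cohort(n = 25, seed = 14)
  m <- init_model(sc$spec, 3, head_width = 5, seed = 8)
  fit <- train_model(m, sc$cohort, hyperparams(epochs = 3, batch_size = 25))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit$model, f)
  back <- read_model(f)
  expect_equal(predict_risk(back, sc$cohort)$risk,
               predict_risk(fit$model, sc$cohort)$risk, tolerance = 1e-12)
})
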