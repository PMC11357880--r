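test_that("GPI score is the impact-weighted alteration sum", {
  co <- cohort_table(c("a", "b", "c"),
                     matrix(c(1, 0, 0, 1, 1, 0), 3,
                            dimnames = list(NULL, c("K1", "K2"))),
                     NULL, time = 1:3, event = c(1L, 1L, 1L))
  imp <- data.frame(feature = c("K1", "K2"), impact = c(0.05, -0.02))
  sc <- gpi_score(co, imp, c("K1", "K2"))
  expect_equal(unname(sc), c(0.05 - 0.02, -0.02, 0))
  expect_equal(unname(gpi_score(co, imp, "K1")), c(0.05, 0, 0))
  expect_error(gpi_score(co, imp, c("K1", "KX")), "KX")
  # random instance vs brute-force dot product
  withr::with_seed(13, {
    n <- 20; p <- 8
    X <- matrix(rbinom(n * p, 1, 0.4), n,
                dimnames = list(NULL, paste0("F", 1:p)))
    coh <- cohort_table(paste0("p", 1:n), X, NULL, rexp(n) + 1, rep(1L, n))
    w <- rnorm(p)
    impt <- data.frame(feature = colnames(X), impact = w)
    got <- gpi_score(coh, impt, colnames(X))
    want <- as.numeric(X %*% w)
    expect_equal(unname(got), want, tolerance = 1e-12)
  })
  # linearity over disjoint-support profiles
  expect_equal(gpi_score(co, imp, c("K1", "K2")),
               gpi_score(co, imp, "K1") + gpi_score(co, imp, "K2"))
})

test_that("level assignment uses the printed thresholds and boundary rule", {
  t1 <- -0.015; t2 <- 0.025
  expect_equal(as.character(assign_levels(0, t1, t2)), "II")
  expect_equal(as.character(assign_levels(0.025, t1, t2)), "II")  # boundary down
  expect_equal(as.character(assign_levels(-0.015, t1, t2)), "I")
  expect_equal(as.character(assign_levels(0.03, t1, t2)), "III")
  expect_equal(as.character(assign_levels(-0.1, t1, t2)), "I")
  expect_error(assign_levels(0, 0.5, 0.5), "t1 < t2")
  # every score set is partitioned
  sc <- withr::with_seed(3, rnorm(100, 0, 0.05))
  lev <- assign_levels(sc, t1, t2)
  expect_equal(sum(table(lev)), 100)
  expect_false(anyNA(lev))
})

test_that("threshold search recovers planted cutpoints between separated strata", {
  withr::with_seed(29, {
    n <- 60
    scores <- c(runif(n, -1, -0.5), runif(n, 0, 0.2), runif(n, 0.8, 1.2))
    haz <- rep(c(0.2, 1, 5), each = n)
    tt <- rexp(3 * n, haz)
    ev <- rep(1L, 3 * n)
    opt <- optimize_thresholds(scores, tt, ev,
                               grid = c(-0.7, -0.3, 0.1, 0.5, 1.0),
                               min_group = 10)
    # planted gaps are (-0.5, 0) and (0.2, 0.8): only -0.3 and 0.5 fall there
    expect_equal(opt$t1, -0.3)
    expect_equal(opt$t2, 0.5)
    expect_lt(opt$worst_p, 1e-6)
  })
  expect_error(optimize_thresholds(rep(1, 30), rexp(30), rep(1L, 30),
                                   grid = c(0, 1), min_group = 5),
               "no admissible")
})

test_that("pairwise interactions match the hypergeometric oracle and label correctly", {
  # identical columns -> strong co-occurrence with infinite odds ratio
  X <- matrix(c(rep(1, 10), rep(0, 10)), 20, 2,
              dimnames = list(NULL, c("A", "B")))
  co <- cohort_table(paste0("p", 1:20), X, NULL, rexp(20) + 1, rep(1L, 20))
  it <- pairwise_interactions(co, alpha = 0.05)
  expect_equal(it$odds_ratio, Inf)
  expect_identical(it$label, "co-occurrence")
  expect_equal(it$p_value, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-12)
  # fisher p equals enumeration over random small tables
  withr::with_seed(37, {
    for (rep in 1:30) {
      n <- sample(8:40, 1)
      x <- rbinom(n, 1, runif(1, 0.2, 0.8))
      y <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      coh <- cohort_table(paste0("q", 1:n),
                          cbind(A = x, B = y), NULL, rexp(n) + 1, rep(1L, n))
      got <- pairwise_interactions(coh)
      a <- sum(x & y); b <- sum(x & !y); c_ <- sum(!x & y); d <- sum(!x & !y)
      expect_equal(got$p_value, oracle_fisher_p(a, b, c_, d),
                   tolerance = 1e-9)
      expect_gte(got$q_value, got$p_value)
    }
  })
  # q >= p and a feature is never tested against itself
  expect_equal(nrow(it), 1)
})

test_that("independent features are rarely labelled after FDR", {
  frac <- withr::with_seed(43, vapply(1:50, function(i) {
    n <- 200
    X <- matrix(rbinom(n * 6, 1, 0.3), n,
                dimnames = list(NULL, paste0("F", 1:6)))
    coh <- cohort_table(paste0("p", 1:n), X, NULL, rexp(n) + 1, rep(1L, n))
    it <- pairwise_interactions(coh, alpha = 0.05)
    mean(it$label != "none")
  }, numeric(1)))
  expect_lte(mean(frac), 0.05 + 0.05)
})

test_that("intersection counts use exclusive patterns and partition the cohort", {
  X <- matrix(c(1, 1, 0,
                1, 0, 0), 3, 2,
              dimnames = list(NULL, c("A", "B")))
  co <- cohort_table(c("x", "y", "z"), X, NULL, 1:3, rep(1L, 3))
  ic <- intersection_counts(co, c("A", "B"))
  expect_equal(nrow(ic), 3)
  expect_equal(sum(ic$count), 3)
  expect_equal(ic$count[ic$pattern == "A+B"], 1)
  expect_equal(ic$count[ic$pattern == "A"], 1)
  expect_equal(ic$count[ic$pattern == "(none)"], 1)
  # random instance vs exhaustive tally
  withr::with_seed(47, {
    n <- 60
    X4 <- matrix(rbinom(n * 4, 1, 0.4), n,
                 dimnames = list(NULL, paste0("F", 1:4)))
    coh <- cohort_table(paste0("p", 1:n), X4, NULL, rexp(n) + 1, rep(1L, n))
    ic4 <- intersection_counts(coh, paste0("F", 1:4))
    expect_equal(sum(ic4$count), n)
    key <- apply(X4, 1, paste, collapse = "")
    for (r in seq_len(nrow(ic4))) {
      pat <- paste(as.integer(ic4[r, paste0("F", 1:4)]), collapse = "")
      expect_equal(ic4$count[r], sum(key == pat))
    }
  })
})

test_that("subtype assignment follows the marker rules", {
  X <- matrix(c(1, 0, 0, 1, 0,
                0, 0, 1, 1, 0,
                0, 1, 0, 0, 0), 5, 3,
              dimnames = list(NULL, c("H_a", "L_a", "H_b")))
  co <- cohort_table(paste0("p", 1:5), X, NULL, 1:5, rep(1L, 5))
  st <- assign_subtypes(co, h1_markers = c("H_a", "H_b"), l1_markers = "L_a")
  expect_equal(as.character(st$subtype), c("H1", "H1", "L1", "both",
                                           "unclassified"))
  expect_error(assign_subtypes(co, c("H_a", "L_a"), "L_a"), "overlap")
  expect_error(assign_subtypes(co, "H_a", "NOPE"), "NOPE")
  # assignments depend only on marker columns
  co2 <- co
  co2$features[, "H_b"] <- rev(co2$features[, "H_b"])
  st2 <- assign_subtypes(co2, "H_a", "L_a")
  st1 <- assign_subtypes(co, "H_a", "L_a")
  expect_identical(st1$subtype, st2$subtype)
})

test_that("sub-subtype by anchor SHAP rank matches a sort oracle", {
  withr::with_seed(53, {
    n <- 30; p <- 8
    X <- matrix(rbinom(n * p, 1, 0.5), n,
                dimnames = list(NULL, paste0("G", 1:p)))
    X[1:3, "G1"] <- 1
    co <- cohort_table(paste0("p", 1:n), X, NULL, rexp(n) + 1, rep(1L, n))
    S <- matrix(rnorm(n * p), n, dimnames = list(co$patient_id, colnames(X)))
    sh <- structure(list(values = S, base_value = 0, node_names = colnames(X),
                         scope = "inputs"), class = "shap_matrix")
    res <- sub_subtype_by_shap_rank(sh, co, "G1", top_k = 5)
    carriers <- which(X[, "G1"] == 1)
    expect_equal(nrow(res), length(carriers))
    for (r in seq_len(nrow(res))) {
      i <- carriers[r]
      want_rank <- sum(abs(S[i, ]) > abs(S[i, "G1"])) + 1L
      expect_equal(res$anchor_rank[r], want_rank)
      expect_equal(as.character(res$sub_subtype[r]),
                   if (want_rank <= 5) "II" else "I")
    }
  })
  # anchor with zero |SHAP| among stronger features ranks bottom -> I
  co1 <- cohort_table("a", matrix(1, 1, 7,
                                  dimnames = list(NULL, paste0("G", 1:7))),
                      NULL, 1, 1L)
  S1 <- matrix(c(0, 1, 2, 3, 4, 5, 6), 1,
               dimnames = list("a", paste0("G", 1:7)))
  sh1 <- structure(list(values = S1, base_value = 0), class = "shap_matrix")
  res1 <- sub_subtype_by_shap_rank(sh1, co1, "G1", top_k = 5)
  expect_equal(as.character(res1$sub_subtype), "I")
  # anchor dominant -> rank 1 -> II
  res2 <- sub_subtype_by_shap_rank(sh1, co1, "G7", top_k = 5)
  expect_equal(res2$anchor_rank, 1L)
  expect_equal(as.character(res2$sub_subtype), "II")
  expect_error(sub_subtype_by_shap_rank(sh1, co1, "GX"), "GX")
})
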