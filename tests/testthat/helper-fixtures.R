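# Shared fixtures and independent oracles. Oracles are deliberately
# naive (explicit enumeration) and never reuse the package's internals.

# -- tiny deterministic inputs ------------------------------------------

tiny_gene_sets <- function() {
  gene_set_collection(list(P1 = c("G1", "G2"), P2 = "G3", P3 = "G2"))
}

tiny_hierarchy <- function() {
  hierarchy_edges(child = c("P1", "P2"), parent = c("P2", "P3"))
}

tiny_cohort <- function(n = 6, p = 3, seed = 42, clinical = TRUE) {
  withr::with_seed(seed, {
    feats <- matrix(rbinom(n * p, 1, 0.5), n,
                    dimnames = list(NULL, paste0("G", seq_len(p))))
    clin <- if (clinical) {
      matrix(rbinom(n * 2, 1, 0.5), n,
             dimnames = list(NULL, c("age_gt_60", "rchop")))
    } else NULL
    cohort_table(paste0("pt", seq_len(n)), feats, clin,
                 time = rexp(n, 1 / 100) + 1,
                 event = c(1, rbinom(n - 1, 1, 0.7)))
  })
}

# A small trained model over a random hierarchy, for attribution tests.
toy_trained_model <- function(n = 25, n_genes = 6, seed = 7, epochs = 5,
                              activation = "tanh") {
  hier <- simulate_hierarchy(4, n_genes, 2, seed = seed)
  genes <- sort(unique(unlist(hier$gene_sets)))
  truth <- ground_truth(stats::setNames(numeric(length(genes)), genes),
                        seed = seed)
  sim <- simulate_cohort(n, stats::setNames(rep(0.4, length(genes)), genes),
                         truth, clinical_freqs = NULL)
  spec <- build_vnn_spec(hier$gene_sets, hier$hierarchy, genes)
  mdl <- init_model(spec, 0, head_width = 6, activation = activation,
                    seed = seed)
  fit <- train_model(mdl, sim$cohort,
                     hyperparams(epochs = epochs, batch_size = n,
                                 seed = seed))
  list(model = fit$model, cohort = sim$cohort, spec = spec, hier = hier)
}

# -- independent oracles ------------------------------------------------

# Negative log partial likelihood by explicit risk-set enumeration.
oracle_cox_loss <- function(r, time, event) {
  total <- 0
  for (i in seq_along(r)) {
    if (event[i] == 1) {
      rs <- which(time >= time[i])
      total <- total + (r[i] - log(sum(exp(r[rs]))))
    }
  }
  -total
}

# C-index by exhaustive double-loop pair counting.
oracle_c_index <- function(r, time, event, half = FALSE) {
  num <- 0; den <- 0
  for (i in seq_along(r)) {
    if (event[i] != 1) next
    for (j in seq_along(r)) {
      if (j == i || time[j] < time[i]) next
      den <- den + 1
      if (r[i] > r[j]) num <- num + 1
      else if (half && r[i] == r[j]) num <- num + 0.5
    }
  }
  list(value = num / den, n_effective = den)
}

# Longest-path layer assignment by exhaustive path enumeration.
oracle_layers <- function(nodes, edges) {
  longest_below <- function(p) {
    ch <- edges$child[edges$parent == p]
    if (length(ch) == 0) return(1L)
    1L + max(vapply(ch, longest_below, integer(1)))
  }
  stats::setNames(vapply(nodes, longest_below, integer(1)), nodes)
}

# Exact Shapley values for one patient over input columns, by direct
# subset enumeration of the interventional value function.
oracle_shapley_inputs <- function(model, cohort, background, i) {
  x <- cbind(cohort$features, cohort$clinical)[i, ]
  B <- cbind(background$features, background$clinical)
  p <- length(x)
  vfun <- function(S) {
    vals <- vapply(seq_len(nrow(B)), function(b) {
      h <- B[b, ]
      h[S] <- x[S]
      hc <- cohort_table("h", t(h[seq_len(ncol(cohort$features))]),
                         if (ncol(cohort$clinical) > 0)
                           t(h[-seq_len(ncol(cohort$features))]) else NULL,
                         time = 1, event = 1L)
      predict_risk(model, hc)$risk
    }, numeric(1))
    mean(vals)
  }
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (m in 0:(2^(p - 1) - 1)) {
      S <- others[bitwAnd(m, bitwShiftL(1, seq_len(p - 1) - 1)) != 0]
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[j] <- phi[j] + w * (vfun(c(S, j)) - vfun(S))
    }
  }
  names(phi) <- c(colnames(cohort$features), colnames(cohort$clinical))
  phi
}

# Two-sided Fisher exact p-value by hypergeometric enumeration.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_dag <- function(n_nodes, p_edge = 0.3, seed = 1) {
  withr::with_seed(seed, {
    nodes <- paste0("N", seq_len(n_nodes))
    child <- character(0); parent <- character(0)
    for (i in seq_len(n_nodes - 1)) {
      for (j in (i + 1):n_nodes) {
        if (runif(1) < p_edge) {
          child <- c(child, nodes[i]); parent <- c(parent, nodes[j])
        }
      }
    }
    list(nodes = nodes,
         edges = data.frame(child = child, parent = parent,
                            stringsAsFactors = FALSE))
  })
}
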