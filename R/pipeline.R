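# End-to-end orchestration: simulate (optional) -> architecture ->
# train -> explain -> impact -> stratify, with a manifest recording the
# config snapshot, seeds and a digest of every artifact so that reruns
# skip up-to-date stages and a corrupted intermediate is caught.

digest_file <- function(path) unname(tools::md5sum(path))

#' Run the full modelling pipeline
#'
#' Stages (in dependency order): `simulate` (optional; emits cohort,
#' gene sets, hierarchy from the synthetic generator), `architecture`
#' (compile the masked spec), `train` (fit the network), `explain`
#' (input-scope SHAP), `impact` (altered-cases impact table),
#' `stratify` (GPI scores and levels). A stage is skipped when its
#' recorded outputs exist with unchanged digests and its inputs are
#' unchanged; a mismatching digest raises an error naming the file.
#' All randomness derives from one master seed, expanded per stage.
#'
#' @param config Either a path to a YAML file or a named list. Keys:
#'   `out_dir` (required), `seed`, `stages` (subset of the above,
#'   default all), `simulate` (list: `n`, `n_features`, `n_pathways`,
#'   `max_depth`, ...), or `cohort`/`gene_sets`/`hierarchy` file paths
#'   when not simulating; `train` (list: hyperparameters), `explain`
#'   (list: `n_samples`, `background`), `stratify` (list: `f_key`
#'   feature names or `top_n`, `t1`, `t2` or a `grid` to search).
#' @return The run manifest (also written to `manifest.json` in
#'   `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stopf("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||%
    c("simulate", "architecture", "train", "explain", "impact", "stratify")
  seeds <- derive_seeds(seed, 6)
  names(seeds) <- c("simulate", "architecture", "train", "explain",
                    "impact", "stratify")
  man_path <- file.path(out_dir, "manifest.json")
  prev <- if (file.exists(man_path)) {
    tryCatch(jsonlite::read_json(man_path, simplifyVector = TRUE),
             error = function(e) NULL)
  } else NULL
  manifest <- list(version = as.character(utils::packageVersion("vnnsurv")),
                   seed = seed, stage_seeds = as.list(seeds),
                   config = config, stages = list())
  paths <- list()

  up_to_date <- function(stage, outs) {
    rec <- prev$stages[[stage]]
    if (is.null(rec) || !setequal(names(rec$outputs), outs)) return(FALSE)
    all(vapply(names(rec$outputs), function(f) {
      if (!file.exists(f)) return(FALSE)
      if (!identical(digest_file(f), rec$outputs[[f]])) {
        stopf("digest mismatch for %s (stage '%s'): file was modified outside the pipeline",
              f, stage)
      }
      TRUE
    }, logical(1)))
  }
  record <- function(stage, outs) {
    manifest$stages[[stage]] <<- list(
      outputs = stats::setNames(as.list(vapply(outs, digest_file,
                                               character(1))), outs))
  }
  require_input <- function(path, stage) {
    if (is.null(path) || !file.exists(path)) {
      stopf("stage '%s' is missing its upstream artifact: %s",
            stage, path %||% "(unset)")
    }
    if (!is.null(prev)) {
      for (st in names(prev$stages)) {
        rec <- prev$stages[[st]]$outputs
        if (path %in% names(rec) &&
            !identical(digest_file(path), rec[[path]])) {
          stopf("digest mismatch for %s (produced by stage '%s'): file was modified",
                path, st)
        }
      }
    }
    path
  }

  # --- simulate ---------------------------------------------------------
  if ("simulate" %in% stages) {
    sim <- config$simulate %||% list()
    paths$cohort <- file.path(out_dir, "cohort.tsv")
    paths$gmt <- file.path(out_dir, "gene_sets.gmt")
    paths$hierarchy <- file.path(out_dir, "hierarchy.tsv")
    paths$truth <- file.path(out_dir, "truth.tsv")
    outs <- unlist(paths[c("cohort", "gmt", "hierarchy", "truth")])
    if (up_to_date("simulate", outs)) {
      manifest$stages$simulate <- prev$stages$simulate
      message("simulate: up to date, skipped")
    } else {
      nfeat <- sim$n_features %||% 30L
      hier <- simulate_hierarchy(sim$n_pathways %||% 20L, nfeat,
                                 sim$max_depth %||% 4L,
                                 seed = seeds[["simulate"]])
      genes <- sort(unique(unlist(hier$gene_sets)))
      n_signal <- sim$n_signal %||% max(1L, round(nfeat / 4))
      beta <- stats::setNames(numeric(length(genes)), genes)
      sig <- genes[seq_len(min(n_signal, length(genes)))]
      beta[sig] <- (sim$beta %||% log(2)) *
        rep_len(c(1, -1), length(sig))
      tr <- ground_truth(beta,
                         clinical_effects = c(age_gt_60 = 0.7,
                                              rchop = -0.7,
                                              de_novo = -0.35),
                         censor_rate_target = sim$censor_rate %||% 0.3,
                         seed = seeds[["simulate"]])
      freqs <- stats::setNames(rep_len(sim$freq %||% 0.3, length(genes)),
                               genes)
      out <- simulate_cohort(sim$n %||% 600L, freqs, tr)
      write_cohort(out$cohort, paths$cohort)
      write_gene_sets(hier$gene_sets, paths$gmt)
      write_hierarchy(hier$hierarchy, paths$hierarchy)
      write_results(data.frame(feature = names(beta), true_beta = beta),
                    paths$truth)
      record("simulate", outs)
    }
  } else {
    paths$cohort <- config$cohort
    paths$gmt <- config$gene_sets
    paths$hierarchy <- config$hierarchy
  }

  cohort <- NULL
  load_cohort <- function() {
    if (is.null(cohort)) {
      cohort <<- read_cohort(require_input(paths$cohort, "architecture"))
    }
    cohort
  }

  # --- architecture -----------------------------------------------------
  paths$spec <- file.path(out_dir, "vnn_spec.json")
  if ("architecture" %in% stages) {
    if (up_to_date("architecture", paths$spec)) {
      manifest$stages$architecture <- prev$stages$architecture
      message("architecture: up to date, skipped")
    } else {
      gs <- read_gene_sets(require_input(paths$gmt, "architecture"))
      hi <- read_hierarchy(require_input(paths$hierarchy, "architecture"))
      spec <- build_vnn_spec(gs, hi, load_cohort()$feature_names,
                             node_width = config$node_width %||% 1L)
      write_vnn_spec(spec, paths$spec)
      record("architecture", paths$spec)
    }
  }

  # --- train ------------------------------------------------------------
  paths$model <- file.path(out_dir, "model.json")
  paths$risks <- file.path(out_dir, "risks.tsv")
  if ("train" %in% stages) {
    outs <- unlist(paths[c("model", "risks")])
    if (up_to_date("train", outs)) {
      manifest$stages$train <- prev$stages$train
      message("train: up to date, skipped")
    } else {
      spec <- read_vnn_spec(require_input(paths$spec, "train"))
      co <- load_cohort()
      tc <- config$train %||% list()
      hp <- do.call(hyperparams, c(tc[intersect(names(tc),
        c("learning_rate", "weight_decay", "batch_size", "epochs",
          "dropout_rate"))], list(seed = seeds[["train"]])))
      hp$batch_size <- min(hp$batch_size, n_patients(co))
      mdl <- init_model(spec, ncol(co$clinical),
                        head_width = tc$head_width %||% 64L,
                        dropout = hp$dropout_rate,
                        seed = seeds[["train"]])
      fit <- train_model(mdl, co, hp)
      write_model(fit$model, paths$model)
      write_results(predict_risk(fit$model, co), paths$risks)
      record("train", outs)
    }
  }

  # --- explain ----------------------------------------------------------
  paths$shap <- file.path(out_dir, "shap_inputs.tsv")
  if ("explain" %in% stages) {
    if (up_to_date("explain", paths$shap)) {
      manifest$stages$explain <- prev$stages$explain
      message("explain: up to date, skipped")
    } else {
      mdl <- read_model(require_input(paths$model, "explain"))
      co <- load_cohort()
      ec <- config$explain %||% list()
      bg <- background_cohort(co, ec$n_background %||% 50L,
                              type = ec$background %||% "zeros",
                              seed = seeds[["explain"]])
      sh <- shap_values(mdl, co, bg, scope = "inputs", method = "sampling",
                        n_samples = ec$n_samples %||% 1024L,
                        seed = seeds[["explain"]])
      df <- data.frame(patient_id = co$patient_id,
                       base_value = rep(sh$base_value,
                                        length.out = n_patients(co)),
                       sh$values, check.names = FALSE)
      write_results(df, paths$shap)
      record("explain", paths$shap)
    }
  }

  # --- impact -----------------------------------------------------------
  paths$impact <- file.path(out_dir, "impact.tsv")
  if ("impact" %in% stages) {
    if (up_to_date("impact", paths$impact)) {
      manifest$stages$impact <- prev$stages$impact
      message("impact: up to date, skipped")
    } else {
      co <- load_cohort()
      df <- read_results(require_input(paths$shap, "impact"))
      S <- as.matrix(df[, setdiff(names(df), c("patient_id", "base_value")),
                        drop = FALSE])
      rownames(S) <- df$patient_id
      imp <- feature_impact(S, co)
      write_results(imp, paths$impact)
      record("impact", paths$impact)
    }
  }

  # --- stratify ---------------------------------------------------------
  paths$gpi <- file.path(out_dir, "gpi.tsv")
  if ("stratify" %in% stages) {
    if (up_to_date("stratify", paths$gpi)) {
      manifest$stages$stratify <- prev$stages$stratify
      message("stratify: up to date, skipped")
    } else {
      co <- load_cohort()
      imp <- read_results(require_input(paths$impact, "stratify"))
      sc <- config$stratify %||% list()
      f_key <- sc$f_key %||% utils::head(imp$feature, sc$top_n %||% 10L)
      scores <- gpi_score(co, imp, f_key)
      if (!is.null(sc$t1) && !is.null(sc$t2)) {
        t1 <- sc$t1; t2 <- sc$t2
      } else {
        qs <- stats::quantile(scores, seq(0.1, 0.9, by = 0.1), names = FALSE)
        opt <- optimize_thresholds(scores, co$time, co$event,
                                   grid = unique(qs),
                                   min_group = sc$min_group %||% 5L)
        t1 <- opt$t1; t2 <- opt$t2
      }
      lev <- assign_levels(scores, t1, t2)
      write_results(data.frame(patient_id = co$patient_id, score = scores,
                               level = as.character(lev), t1 = t1, t2 = t2),
                    paths$gpi)
      record("stratify", paths$gpi)
    }
  }

  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
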