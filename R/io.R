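# Cohort, gene-set (GMT) and hierarchy (edge-list) readers, plus writers
# for the result tables produced downstream. All files are UTF-8 TSV with
# "." decimal; GMT follows the de-facto standard (id, description, members).

#' Construct a cohort table
#'
#' The central container consumed by every other stage: a binary
#' gene-alteration matrix, binary clinical covariates, survival times in
#' days and event indicators (1 = death observed).
#'
#' @param patient_id Character vector of unique patient identifiers.
#' @param features Integer/numeric matrix of 0/1 alteration indicators,
#'   rows = patients, named columns = genetic features.
#' @param clinical Matrix of 0/1 clinical covariates with named columns
#'   (may have zero columns). Conventional columns are `age_gt_60`,
#'   `rchop` and `de_novo`; encoding binarization (age cutpoint etc.) is
#'   done upstream.
#' @param time Positive survival/follow-up times (days).
#' @param event 0/1 event indicators (1 = death observed).
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(patient_id, features, clinical = NULL, time, event) {
  n <- length(patient_id)
  features <- as.matrix(features)
  if (is.null(clinical)) {
    clinical <- matrix(0, n, 0)
  }
  clinical <- as.matrix(clinical)
  if (anyDuplicated(patient_id)) stopf("duplicated patient ids")
  if (nrow(features) != n || nrow(clinical) != n ||
      length(time) != n || length(event) != n) {
    stopf("cohort components disagree on the number of patients")
  }
  if (ncol(features) > 0 && is.null(colnames(features))) {
    stopf("feature columns must be named")
  }
  if (anyDuplicated(colnames(features))) stopf("feature names must be unique")
  if (ncol(clinical) > 0 && is.null(colnames(clinical))) {
    stopf("clinical columns must be named")
  }
  check_binary_matrix(features, "feature")
  check_binary_matrix(clinical, "clinical")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stopf("time must be positive and finite for all patients")
  }
  if (!is_binary(event)) stopf("event must be 0/1")
  structure(
    list(patient_id = as.character(patient_id),
         features = matrix(as.numeric(features), n,
                           dimnames = list(patient_id, colnames(features)),
                           ncol = ncol(features)),
         clinical = matrix(as.numeric(clinical), n,
                           dimnames = list(patient_id, colnames(clinical)),
                           ncol = ncol(clinical)),
         time = as.numeric(time),
         event = as.integer(event),
         feature_names = colnames(features) %||% character(0)),
    class = "cohort_table")
}

check_binary_matrix <- function(m, what) {
  if (length(m) == 0) return(invisible(TRUE))
  bad <- which(is.na(m) | (m != 0 & m != 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("non-binary %s value at row %d, column '%s' (value %s)",
          what, bad[1, 1],
          colnames(m)[bad[1, 2]] %||% as.character(bad[1, 2]),
          format(m[bad[1, 1], bad[1, 2]]))
  }
  invisible(TRUE)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d patients, %d genetic features, %d clinical covariates\n",
              length(x$patient_id), ncol(x$features), ncol(x$clinical)))
  cat(sprintf("  events: %d observed / %d censored; median follow-up %.0f days\n",
              sum(x$event), sum(1 - x$event), stats::median(x$time)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort A `cohort_table`.
#' @return Integer patient count.
#' @export
n_patients <- function(cohort) length(cohort$patient_id)

#' Read a cohort table from TSV
#'
#' Expects a header row with columns `patient_id`, one column per binary
#' feature/covariate, and `time` and `event`. Columns whose names appear
#' in `clinical_cols` are treated as clinical covariates; all other binary
#' columns are genetic features. Features requested via `missing_default`
#' but absent from the file are appended as constant columns with the
#' stated default (the convention for harmonizing panels that did not
#' assay a given gene: all patients receive the same imputed 0 or 1).
#'
#' @param path Path to a TSV file.
#' @param missing_default Named list/vector mapping feature name to 0 or 1.
#'   Features already present in the file are left untouched.
#' @param clinical_cols Column names to treat as clinical covariates.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, missing_default = NULL,
                        clinical_cols = c("age_gt_60", "rchop", "de_novo")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stopf("cohort file lacks column(s): %s",
                              paste(miss, collapse = ", "))
  pid <- if ("patient_id" %in% names(df)) as.character(df$patient_id) else
    sprintf("P%04d", seq_len(nrow(df)))
  if (any(df$time <= 0, na.rm = TRUE) || anyNA(df$time)) {
    stopf("time must be positive for all rows (first bad row: %d)",
          which(is.na(df$time) | df$time <= 0)[1])
  }
  val_cols <- setdiff(names(df), c("patient_id", "time", "event"))
  clin <- intersect(clinical_cols, val_cols)
  feat <- setdiff(val_cols, clin)
  fm <- as.matrix(df[, feat, drop = FALSE])
  cm <- as.matrix(df[, clin, drop = FALSE])
  if (!is.null(missing_default)) {
    md <- unlist(missing_default)
    if (!all(md %in% c(0, 1))) stopf("missing_default values must be 0 or 1")
    add <- setdiff(names(md), colnames(fm))
    for (f in add) {
      fm <- cbind(fm, matrix(md[[f]], nrow(fm), 1,
                             dimnames = list(NULL, f)))
    }
  }
  cohort_table(patient_id = pid, features = fm, clinical = cm,
               time = df$time, event = df$event)
}

#' Write a cohort table to TSV
#'
#' Inverse of [read_cohort()]: columns `patient_id`, features, clinical,
#' `time`, `event`, in that order.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(patient_id = cohort$patient_id, check.names = FALSE)
  if (ncol(cohort$features) > 0) df <- cbind(df, as.data.frame(cohort$features))
  if (ncol(cohort$clinical) > 0) df <- cbind(df, as.data.frame(cohort$clinical))
  df$time <- cohort$time
  df$event <- cohort$event
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection (GMT)
#'
#' One line per set: `id<TAB>description<TAB>member1<TAB>member2...`.
#' The description field is discarded and duplicate members within a line
#' are deduplicated.
#'
#' @param path Path to a GMT file.
#' @return Named list mapping pathway id to a character vector of unique
#'   member gene symbols (class `gene_set_collection`).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stopf("GMT line %d has %d field(s); need id, description, >=1 member",
            i, length(fields))
    }
    id <- fields[[1]]
    if (id %in% names(sets)) stopf("duplicate pathway id '%s' at line %d", id, i)
    sets[[id]] <- unique(fields[-(1:2)])
  }
  gene_set_collection(sets)
}

#' Construct/validate a gene-set collection
#' @param sets Named list of character vectors (pathway id -> members).
#' @return The validated collection, class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (length(sets) > 0 && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stopf("every gene set needs a pathway id")
  }
  if (anyDuplicated(names(sets))) stopf("pathway ids must be unique")
  if (any(lengths(sets) == 0)) {
    stopf("empty member set for pathway '%s'",
          names(sets)[which(lengths(sets) == 0)[1]])
  }
  structure(lapply(sets, unique), class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param sets A `gene_set_collection` (or plain named list).
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions;
#'   defaults to "na".
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[id] %||% "na", sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pathway hierarchy edge list
#'
#' Two-column TSV `child<TAB>parent` (an optional header line
#' `child  parent` is skipped). Duplicate edges are collapsed; self-edges
#' are rejected. Acyclicity is verified downstream when the graph is
#' built.
#'
#' @param path Path to the edge-list TSV.
#' @return data.frame with columns `child`, `parent`
#'   (class `hierarchy_edges`).
#' @export
read_hierarchy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0) {
    first <- tolower(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
    if (identical(first, c("child", "parent"))) lines <- lines[-1]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) stopf("malformed hierarchy line %d: need 2 fields", bad[1])
  child <- vapply(parts, `[[`, character(1), 1)
  parent <- vapply(parts, `[[`, character(1), 2)
  hierarchy_edges(child, parent)
}

#' Construct/validate hierarchy edges
#' @param child,parent Character vectors of pathway ids (child -> parent).
#' @return data.frame of unique edges, class `hierarchy_edges`.
#' @export
hierarchy_edges <- function(child, parent) {
  self <- which(child == parent)
  if (length(self) > 0) {
    stopf("self-edge '%s' -> itself is not allowed", child[self[1]])
  }
  df <- unique(data.frame(child = as.character(child),
                          parent = as.character(parent),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("hierarchy_edges", "data.frame")
  df
}

#' Write hierarchy edges to TSV
#' @param edges A `hierarchy_edges` data.frame.
#' @param path Output path.
#' @param header Write a `child  parent` header line?
#' @return Invisibly, `path`.
#' @export
write_hierarchy <- function(edges, path, header = TRUE) {
  utils::write.table(as.data.frame(edges)[, c("child", "parent")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

#' Write a result table to TSV
#'
#' Generic writer for the tabular results produced by the pipeline
#' (risk tables, impact tables, GPI results, interaction tables, ...).
#' Numeric columns are written at full precision so that
#' `read_results(write_results(x))` round-trips to 1e-10.
#'
#' @param table A data.frame (or `sankey_graph`, which dispatches to
#'   [write_sankey()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  if (inherits(table, "sankey_graph")) return(write_sankey(table, path))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path Path to the TSV.
#' @return data.frame with numeric columns restored.
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1)
  if (identical(first, "# sankey v1")) return(read_sankey(path))
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
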