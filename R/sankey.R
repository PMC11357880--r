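# Multilayered Sankey graph over the visible architecture: node widths
# are mean |SHAP| across patients; each target's incoming edges split the
# target's width proportionally to its sources' widths, so widths are
# conserved before pruning.

#' Build a Sankey graph from SHAP attributions over the architecture
#'
#' Nodes are the input features (layer 0) and retained pathways (their
#' assigned layers); node width = mean `|SHAP|` over patients. The edge
#' from source `s` to target `t` has width
#' `width(t) * width(s) / sum of widths over t's sources`. A target all
#' of whose sources have zero width keeps zero-width incoming edges and
#' is flagged. Edges strictly below the `prune_fraction` quantile of
#' positive edge widths are then removed.
#'
#' @param spec A `vnn_spec`.
#' @param shap_pathways A pathway-scope `shap_matrix`.
#' @param shap_inputs An input-scope `shap_matrix`.
#' @param prune_fraction Fraction in \[0, 1) of edges to prune.
#' @return A `sankey_graph`: `nodes` (name, kind, layer, width),
#'   `edges` (source, target, width), `flagged` (targets with zero
#'   total source width).
#' @export
build_sankey <- function(spec, shap_pathways, shap_inputs,
                         prune_fraction = 0) {
  if (prune_fraction < 0 || prune_fraction >= 1) {
    stopf("prune_fraction must lie in [0, 1)")
  }
  mean_abs <- function(sm) colMeans(abs(sm$values))
  w_in <- mean_abs(shap_inputs)
  w_pw <- mean_abs(shap_pathways)
  graph <- spec$graph
  genes <- intersect(spec$feature_order, names(w_in))
  nodes <- data.frame(
    name = c(genes, names(spec$layer_of)),
    kind = c(rep("feature", length(genes)),
             rep("pathway", length(spec$layer_of))),
    layer = c(rep(0L, length(genes)), unname(spec$layer_of)),
    width = c(unname(w_in[genes]), unname(w_pw[names(spec$layer_of)])),
    stringsAsFactors = FALSE)

  src_of <- function(p) {
    c(graph$membership[[p]] %||% character(0),
      graph$parent_edges$child[graph$parent_edges$parent == p])
  }
  widths <- stats::setNames(nodes$width, nodes$name)
  edges <- list()
  flagged <- character(0)
  for (p in names(spec$layer_of)) {
    srcs <- intersect(src_of(p), nodes$name)
    if (length(srcs) == 0) next
    tot <- sum(widths[srcs])
    if (tot == 0) {
      flagged <- c(flagged, p)
      ew <- rep(0, length(srcs))
    } else {
      ew <- widths[p] * widths[srcs] / tot
    }
    edges[[p]] <- data.frame(source = srcs, target = p, width = unname(ew),
                             stringsAsFactors = FALSE)
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               width = numeric(0))
  rownames(edges) <- NULL
  if (prune_fraction > 0 && nrow(edges) > 0) {
    cut <- stats::quantile(edges$width, prune_fraction, names = FALSE)
    edges <- edges[edges$width >= cut, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, flagged = flagged,
                 prune_fraction = prune_fraction),
            class = "sankey_graph")
}

#' @export
print.sankey_graph <- function(x, ...) {
  cat(sprintf("sankey_graph: %d nodes, %d edges (prune fraction %.2f, %d zero-input target(s))\n",
              nrow(x$nodes), nrow(x$edges), x$prune_fraction,
              length(x$flagged)))
  invisible(x)
}

#' Write a Sankey graph to a structured text file
#'
#' Sectioned TSV (`[nodes]`, `[edges]`, `[flagged]`) with full-precision
#' widths so that [read_sankey()] round-trips at 1e-10.
#'
#' @param graph A `sankey_graph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sankey <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sankey v1", con)
  writeLines(sprintf("prune_fraction\t%.17g", graph$prune_fraction), con)
  writeLines("[nodes]", con)
  writeLines("name\tkind\tlayer\twidth", con)
  with(graph$nodes,
       writeLines(sprintf("%s\t%s\t%d\t%.17g", name, kind, layer, width), con))
  writeLines("[edges]", con)
  writeLines("source\ttarget\twidth", con)
  with(graph$edges,
       writeLines(sprintf("%s\t%s\t%.17g", source, target, width), con))
  writeLines("[flagged]", con)
  writeLines(graph$flagged, con)
  invisible(path)
}

#' Read a Sankey graph written by [write_sankey()]
#' @param path Path to the file.
#' @return A `sankey_graph`.
#' @export
read_sankey <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(lines[1], "# sankey v1")) stopf("not a sankey graph file")
  pf <- as.numeric(strsplit(lines[2], "\t")[[1]][2])
  sec <- function(name) {
    i <- which(lines == paste0("[", name, "]"))
    ends <- c(grep("^\\[", lines), length(lines) + 1)
    j <- min(ends[ends > i])
    lines[seq.int(i + 1, length.out = max(0, j - i - 1))]
  }
  parse_tsv <- function(txt) {
    if (length(txt) <= 1) return(NULL)
    utils::read.delim(text = paste(txt, collapse = "\n"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  }
  nodes <- parse_tsv(sec("nodes"))
  edges <- parse_tsv(sec("edges"))
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        width = numeric(0))
  }
  flagged <- sec("flagged")
  flagged <- flagged[nzchar(flagged)]
  structure(list(nodes = nodes, edges = edges, flagged = flagged,
                 prune_fraction = pf),
            class = "sankey_graph")
}
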