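# Compilation of gene sets + pathway hierarchy + an input gene panel into
# a layered sparse network specification. Neurons map to genes and
# pathways; a connection exists only where a gene belongs to a pathway or
# a pathway is a child of another. Pathways whose parents lie more than
# one layer up, and genes whose member pathways sit above layer 1, are
# carried by frozen identity "skip-through" channels so that every edge
# of the biological graph is realized between adjacent network layers.

#' Build the pruned pathway graph for an input gene panel
#'
#' Retains exactly the pathways reachable from the input genes: direct
#' membership, then transitive closure along child-to-parent edges.
#' Input genes that belong to no pathway are flagged as orphans (they
#' are later routed straight to the root so no input is discarded).
#'
#' @param gene_sets A `gene_set_collection` (pathway id -> member genes).
#' @param hierarchy A `hierarchy_edges` data.frame (child, parent).
#' @param input_genes Ordered character vector of input feature names.
#' @return A `pathway_graph` list: `nodes`, `membership` (pathway ->
#'   member input genes), `parent_edges`, `roots`, `orphan_genes`,
#'   `input_genes`.
#' @export
build_pathway_graph <- function(gene_sets, hierarchy, input_genes) {
  if (length(input_genes) == 0) stopf("input_genes must be non-empty")
  if (anyDuplicated(input_genes)) stopf("input_genes must be unique")
  membership_all <- lapply(gene_sets, intersect, x = input_genes)
  seed_pw <- names(gene_sets)[lengths(membership_all) > 0]
  orphan <- input_genes[!vapply(input_genes, function(g)
    any(vapply(gene_sets, function(s) g %in% s, logical(1))), logical(1))]
  # transitive closure toward parents
  retained <- seed_pw
  repeat {
    up <- unique(hierarchy$parent[hierarchy$child %in% retained])
    new <- setdiff(up, retained)
    if (length(new) == 0) break
    retained <- c(retained, new)
  }
  if (length(retained) == 0) {
    stopf("no pathway is reachable from the input genes")
  }
  edges <- hierarchy[hierarchy$child %in% retained &
                       hierarchy$parent %in% retained, , drop = FALSE]
  rownames(edges) <- NULL
  check_acyclic(retained, edges)
  roots <- setdiff(retained, edges$child)
  membership <- lapply(membership_all[intersect(names(membership_all), retained)],
                       identity)
  membership <- membership[lengths(membership) > 0]
  structure(
    list(nodes = sort(retained),
         membership = membership,
         parent_edges = as.data.frame(edges)[, c("child", "parent")],
         roots = sort(roots),
         orphan_genes = orphan,
         input_genes = as.character(input_genes)),
    class = "pathway_graph")
}

# Kahn's algorithm; reports a cycle witness on failure.
check_acyclic <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  active <- nodes
  repeat {
    leaf <- active[indeg[active] == 0]
    if (length(leaf) == 0) break
    drop_edges <- edges$parent[edges$child %in% leaf & edges$parent %in% active]
    for (p in drop_edges) indeg[p] <- indeg[p] - 1L
    active <- setdiff(active, leaf)
  }
  if (length(active) > 0) {
    stopf("hierarchy contains a cycle among: %s",
          paste(sort(active), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d pathways (%d roots), %d edges, %d input genes (%d orphans)\n",
              length(x$nodes), length(x$roots), nrow(x$parent_edges),
              length(x$input_genes), length(x$orphan_genes)))
  invisible(x)
}

#' Assign pathways to network layers by longest child-chain
#'
#' `layer(p) = 1 +` length of the longest chain of child edges below `p`
#' within the retained graph; leaf pathways get layer 1. This guarantees
#' `layer(child) < layer(parent)` for every edge (a shortest-path
#' layering can invert edges when the hierarchy is non-strict).
#'
#' @param graph A `pathway_graph`.
#' @return List with `layer_of` (named integer vector) and `n_layers`.
#' @export
assign_layers <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$parent_edges
  children_of <- split(edges$child, edges$parent)
  layer <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  depth <- function(p) {
    if (!is.na(layer[[p]])) return(layer[[p]])
    ch <- children_of[[p]]
    d <- if (is.null(ch)) 1L else 1L + max(vapply(ch, depth, integer(1)))
    layer[[p]] <<- d
    d
  }
  for (p in nodes) depth(p)
  list(layer_of = layer, n_layers = max(layer))
}

#' Compile a sparse visible-network specification
#'
#' Produces, per layer, the binary connectivity mask over the units
#' flowing between layers. Each pathway owns `node_width` neurons. A
#' unit produced at layer `k` but consumed at layer `m > k + 1` (a gene
#' entering a deep pathway, or a child whose parent sits several layers
#' up, or anything bound for the root) travels through frozen identity
#' skip-through channels. Under `root_mode = "concat"` the root embedding
#' is the concatenation of all root-pathway outputs and orphan-gene
#' channels; `"dense"` adds a learnable projection to `root_width`.
#'
#' @param graph A `pathway_graph`.
#' @param layers Output of [assign_layers()] (computed if `NULL`).
#' @param node_width Neurons per pathway (default 1).
#' @param root_mode `"concat"` (root width emerges from the collected
#'   channels) or `"dense"` (project to `root_width`).
#' @param root_width Target dimension under `"dense"` mode.
#' @return A `vnn_spec` list; see Details in the package vignette.
#' @export
build_masks <- function(graph, layers = NULL, node_width = 1L,
                        root_mode = c("concat", "dense"), root_width = NULL) {
  root_mode <- match.arg(root_mode)
  stopifnot(node_width >= 1)
  if (is.null(layers)) layers <- assign_layers(graph)
  layer_of <- layers$layer_of
  if (any(!graph$nodes %in% names(layer_of)) || anyNA(layer_of[graph$nodes])) {
    stopf("every retained pathway needs a layer assignment")
  }
  L <- layers$n_layers
  nw <- as.integer(node_width)

  pw_units <- function(p) if (nw == 1) paste0("p:", p) else
    paste0("p:", p, "#", seq_len(nw))
  gene_unit <- function(g) paste0("g:", g)

  # layer at which each source is last consumed; root sits at L + 1
  member_layers <- lapply(graph$input_genes, function(g) {
    pws <- names(graph$membership)[vapply(graph$membership, function(m)
      g %in% m, logical(1))]
    unname(layer_of[pws])
  })
  names(member_layers) <- graph$input_genes
  last_gene <- vapply(graph$input_genes, function(g) {
    if (g %in% graph$orphan_genes) L + 1L else max(member_layers[[g]])
  }, integer(1))
  parents_of <- split(graph$parent_edges$parent, graph$parent_edges$child)
  last_pw <- vapply(graph$nodes, function(p) {
    if (p %in% graph$roots) L + 1L else max(layer_of[parents_of[[p]]])
  }, integer(1))

  produced <- c(stats::setNames(rep(0L, length(graph$input_genes)),
                                gene_unit(graph$input_genes)))
  last_of <- c(stats::setNames(last_gene, gene_unit(graph$input_genes)))
  unit_owner <- c(stats::setNames(graph$input_genes,
                                  gene_unit(graph$input_genes)))
  for (p in graph$nodes) {
    u <- pw_units(p)
    produced[u] <- layer_of[[p]]
    last_of[u] <- last_pw[[p]]
    unit_owner[u] <- p
  }

  out_units <- function(l) {
    pw <- names(layer_of)[layer_of == l]
    pw <- pw[order(match(pw, graph$nodes))]
    own <- unlist(lapply(pw, pw_units), use.names = FALSE)
    thru <- names(produced)[produced < l & last_of > l]
    thru <- setdiff(thru, own)
    c(own, thru)
  }
  in_names0 <- gene_unit(graph$input_genes)

  layer_specs <- vector("list", L)
  prev <- in_names0
  for (l in seq_len(L)) {
    out <- out_units(l)
    mask <- matrix(0, length(prev), length(out),
                   dimnames = list(prev, out))
    trainable <- matrix(FALSE, length(prev), length(out),
                        dimnames = list(prev, out))
    is_pathway <- startsWith(out, "p:") & produced[out] == l
    for (j in seq_along(out)) {
      u <- out[[j]]
      if (is_pathway[[j]]) {
        p <- unit_owner[[u]]
        srcs <- character(0)
        mem <- graph$membership[[p]]
        if (!is.null(mem)) srcs <- c(srcs, gene_unit(mem))
        ch <- graph$parent_edges$child[graph$parent_edges$parent == p]
        if (length(ch) > 0) {
          srcs <- c(srcs, unlist(lapply(ch, pw_units), use.names = FALSE))
        }
        srcs <- intersect(srcs, prev)
        mask[srcs, j] <- 1
        trainable[srcs, j] <- TRUE
      } else {
        mask[u, j] <- 1  # frozen identity skip-through
      }
    }
    layer_specs[[l]] <- list(in_names = prev, out_names = out,
                             mask = mask, trainable = trainable,
                             is_pathway = is_pathway)
    prev <- out
  }

  root_units <- prev  # output of layer L: root pathways + orphan genes
  structure(
    list(n_layers = L,
         layer_of = layer_of,
         node_width = nw,
         layers = layer_specs,
         feature_order = graph$input_genes,
         orphan_genes = graph$orphan_genes,
         root_units = root_units,
         root_mode = root_mode,
         root_width = if (root_mode == "concat") length(root_units)
                      else as.integer(root_width %||%
                                        stopf("root_width required for dense root mode")),
         graph = graph),
    class = "vnn_spec")
}

#' Compile gene sets + hierarchy straight to a `vnn_spec`
#'
#' Convenience wrapper: [build_pathway_graph()] then [assign_layers()]
#' then [build_masks()].
#'
#' @inheritParams build_pathway_graph
#' @inheritParams build_masks
#' @return A `vnn_spec`.
#' @export
build_vnn_spec <- function(gene_sets, hierarchy, input_genes, node_width = 1L,
                           root_mode = "concat", root_width = NULL) {
  graph <- build_pathway_graph(gene_sets, hierarchy, input_genes)
  build_masks(graph, assign_layers(graph), node_width = node_width,
              root_mode = root_mode, root_width = root_width)
}

#' @export
print.vnn_spec <- function(x, ...) {
  nnz <- sum(vapply(x$layers, function(l) sum(l$trainable), numeric(1)))
  cat(sprintf("vnn_spec: %d input genes -> %d pathways over %d layers -> root width %d (%s)\n",
              length(x$feature_order), length(x$layer_of), x$n_layers,
              x$root_width, x$root_mode))
  cat(sprintf("  %d trainable sparse positions; node_width %d; %d orphan gene(s)\n",
              nnz, x$node_width, length(x$orphan_genes)))
  invisible(x)
}

#' Serialize a `vnn_spec` to structured text (JSON)
#'
#' Masks are stored in sparse triplet form so files remain diff-friendly.
#'
#' @param spec A `vnn_spec`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vnn_spec <- function(spec, path) {
  lay <- lapply(spec$layers, function(l) {
    idx <- which(l$mask == 1, arr.ind = TRUE)
    list(in_names = l$in_names, out_names = l$out_names,
         links = data.frame(src = l$in_names[idx[, 1]],
                            dst = l$out_names[idx[, 2]],
                            trainable = l$trainable[idx]),
         is_pathway = l$is_pathway)
  })
  obj <- list(format = "vnn_spec/1",
              n_layers = spec$n_layers,
              layer_of = as.list(spec$layer_of),
              node_width = spec$node_width,
              feature_order = spec$feature_order,
              orphan_genes = spec$orphan_genes,
              root_units = spec$root_units,
              root_mode = spec$root_mode,
              root_width = spec$root_width,
              membership = spec$graph$membership,
              parent_edges = spec$graph$parent_edges,
              layers = lay)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a `vnn_spec` written by [write_vnn_spec()]
#' @param path Path to the JSON file.
#' @return A `vnn_spec` (rebuilt from the stored graph so that all dense
#'   mask matrices are reconstructed exactly).
#' @export
read_vnn_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vnn_spec/1")) stopf("not a vnn_spec file")
  gs <- gene_set_collection(lapply(obj$membership, as.character))
  hier <- if (length(obj$parent_edges) > 0 && nrow(obj$parent_edges) > 0) {
    hierarchy_edges(obj$parent_edges$child, obj$parent_edges$parent)
  } else {
    hierarchy_edges(character(0), character(0))
  }
  graph <- build_pathway_graph(gs, hier, as.character(obj$feature_order))
  build_masks(graph, node_width = obj$node_width, root_mode = obj$root_mode,
              root_width = obj$root_width)
}
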