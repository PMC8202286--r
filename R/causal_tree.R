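#' Enrich secondary causal terms inside a parent-term stratum
#'
#' Restricts the analysis to reports containing every parent term, then
#' re-runs \code{\link{infer_causes}} over the terms of features not already
#' fixed on the path: the do / not-do comparison is made entirely within the
#' parent stratum. With no parents this reduces exactly to
#' \code{\link{infer_causes}} on the full dataset.
#'
#' @inheritParams infer_causes
#' @param parent_terms named character vector, feature name -> fixed term
#'   (the conditioning path); empty for the root level.
#' @return a \code{causal_terms} object (possibly empty when the stratum is
#'   smaller than twice \code{min_group_size}).
#' @export
infer_secondary_causes <- function(reports, probs, schema,
                                   parent_terms = character(), alpha = 0.05,
                                   min_group_size = 30,
                                   adjust = c("bonferroni", "bh"),
                                   pooled = FALSE) {
  adjust <- match.arg(adjust)
  if (length(parent_terms)) {
    keep <- vapply(reports, function(r) {
      all(vapply(names(parent_terms), function(f)
        parent_terms[[f]] %in% (r$values[[f]] %||% character()), logical(1)))
    }, logical(1))
    reports <- reports[keep]
    if (length(reports) < 2 * min_group_size) {
      message(sprintf("stratum of {%s} has %d reports (< 2 x %d); no secondary terms",
                      paste(names(parent_terms), parent_terms, sep = "=",
                            collapse = ", "),
                      length(reports), min_group_size))
      res <- empty_causal_terms()
      return(structure(res, all_tested = res, root_causes = res,
                       skipped = NULL, alpha = alpha, adjust = adjust,
                       class = c("causal_terms", "data.frame")))
    }
  }
  feats <- setdiff(schema$features,
                   c(schema$endpoint_feature, names(parent_terms)))
  infer_causes(reports, probs, schema, alpha = alpha,
               min_group_size = min_group_size, adjust = adjust,
               pooled = pooled, features = feats)
}

new_tree_node <- function(term, feature, z, p_adj, depth) {
  list(term = term, feature = feature, z = z, p_adj = p_adj,
       depth = depth, children = list())
}

#' Build the recursive causal tree
#'
#' Level 1 is the single enriched term with the globally highest z-score
#' (or, with \code{root_mode = "per-feature"}, the top term of every
#' feature). Each deeper level N re-runs the interventional probe inside
#' each parent's stratum, pools the enriched candidate children of the
#' level, ranks them by z, and retains at most N of them. Recursion stops at
#' \code{max_depth}, at empty enrichment, or at an undersized stratum. A
#' feature already fixed on the path is never re-tested.
#'
#' @inheritParams infer_causes
#' @param max_depth maximum tree depth (root children are depth 1).
#' @param root_mode \code{"global"} for the single highest-z root,
#'   \code{"per-feature"} for one root per clinical feature.
#' @return object of class \code{causal_tree}: a virtual root node whose
#'   \code{children} are the level-1 terms.
#' @export
build_causal_tree <- function(reports, probs, schema, alpha = 0.05,
                              min_group_size = 30,
                              adjust = c("bonferroni", "bh"),
                              max_depth = 3, root_mode = c("global", "per-feature")) {
  adjust <- match.arg(adjust)
  root_mode <- match.arg(root_mode)
  base <- infer_causes(reports, probs, schema, alpha = alpha,
                       min_group_size = min_group_size, adjust = adjust)
  root <- new_tree_node(NA_character_, NA_character_, NA_real_, NA_real_, 0L)
  class(root) <- "causal_tree"
  if (nrow(base) == 0) return(root)
  level1 <- if (root_mode == "global") base[1, , drop = FALSE]
            else attr(base, "root_causes")
  root$children <- lapply(seq_len(nrow(level1)), function(i)
    new_tree_node(level1$term[i], level1$feature[i], level1$z[i],
                  level1$p_adj[i], 1L))
  # breadth-first growth; frontier entries carry the node's path of fixed
  # (feature -> term) pairs and its index path into the tree
  frontier <- lapply(seq_along(root$children), function(i) {
    ch <- root$children[[i]]
    list(path = stats::setNames(ch$term, ch$feature), idx = i)
  })
  depth <- 1L
  while (depth < max_depth && length(frontier)) {
    level <- depth + 1L
    candidates <- list()
    for (fr in frontier) {
      sec <- infer_secondary_causes(reports, probs, schema,
                                    parent_terms = fr$path, alpha = alpha,
                                    min_group_size = min_group_size,
                                    adjust = adjust)
      if (nrow(sec) == 0) next
      for (i in seq_len(nrow(sec))) {
        candidates[[length(candidates) + 1L]] <-
          list(parent = fr, term = sec$term[i], feature = sec$feature[i],
               z = sec$z[i], p_adj = sec$p_adj[i])
      }
    }
    if (!length(candidates)) break
    zs <- vapply(candidates, `[[`, numeric(1), "z")
    terms <- vapply(candidates, `[[`, character(1), "term")
    keep <- order(-zs, terms)[seq_len(min(level, length(candidates)))]
    new_frontier <- list()
    for (ci in keep) {
      cand <- candidates[[ci]]
      node <- new_tree_node(cand$term, cand$feature, cand$z, cand$p_adj, level)
      idx_path <- cand$parent$idx
      root <- attach_child(root, idx_path, node)
      child_pos <- length(tree_get(root, idx_path)$children)
      new_frontier[[length(new_frontier) + 1L]] <-
        list(path = c(cand$parent$path,
                      stats::setNames(cand$term, cand$feature)),
             idx = c(idx_path, child_pos))
    }
    frontier <- new_frontier
    depth <- level
  }
  root
}

tree_get <- function(tree, idx) {
  node <- tree
  for (i in idx) node <- node$children[[i]]
  node
}

attach_child <- function(tree, idx, child) {
  if (length(idx) == 0) {
    tree$children[[length(tree$children) + 1L]] <- child
    return(tree)
  }
  tree$children[[idx[1]]] <- attach_child(tree$children[[idx[1]]],
                                          idx[-1], child)
  tree
}

tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (!is.na(node$term %||% NA))
      out[[length(out) + 1L]] <<- node[c("term", "feature", "z", "p_adj", "depth")]
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  if (!length(out)) return(empty_causal_terms()[, c("feature", "term", "z", "p_adj")])
  df <- do.call(rbind, lapply(out, function(n)
    data.frame(feature = n$feature, term = n$term, z = n$z, p_adj = n$p_adj,
               depth = n$depth, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Edges of a causal tree
#' @param tree a \code{causal_tree}.
#' @return data frame with parent/child feature-term pairs and the child z.
#' @export
tree_edges <- function(tree) {
  out <- list()
  walk <- function(node) {
    for (ch in node$children) {
      out[[length(out) + 1L]] <<-
        data.frame(parent_feature = node$feature, parent_term = node$term,
                   child_feature = ch$feature, child_term = ch$term,
                   z = ch$z, stringsAsFactors = FALSE)
      walk(ch)
    }
  }
  walk(tree)
  if (!length(out))
    return(data.frame(parent_feature = character(), parent_term = character(),
                      child_feature = character(), child_term = character(),
                      z = numeric(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' @export
print.causal_tree <- function(x, digits = 2, ...) {
  if (!length(x$children)) {
    cat("<empty causal tree>\n")
    return(invisible(x))
  }
  cat("Causal tree:\n")
  walk <- function(node, prefix) {
    for (ch in node$children) {
      cat(sprintf("%s%s = %s (z = %s)\n", prefix, ch$feature, ch$term,
                  format(round(ch$z, digits))))
      walk(ch, paste0(prefix, "  "))
    }
  }
  walk(x, "  ")
  invisible(x)
}

#' @export
plot.causal_tree <- function(x, ...) {
  nodes <- tree_nodes(x)
  if (nrow(nodes) == 0) {
    graphics::plot.new()
    graphics::title("Empty causal tree")
    return(invisible(x))
  }
  nodes$label <- paste0(nodes$term, "\nz=", round(nodes$z, 1))
  depths <- nodes$depth
  xs <- stats::ave(seq_len(nrow(nodes)), depths,
                   FUN = function(i) seq_along(i) / (length(i) + 1))
  ys <- 1 - depths / (max(depths) + 1)
  graphics::plot(xs, ys, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  edges <- tree_edges(x)
  key <- paste(nodes$feature, nodes$term)
  for (i in seq_len(nrow(edges))) {
    if (is.na(edges$parent_term[i])) next
    pi <- match(paste(edges$parent_feature[i], edges$parent_term[i]), key)
    ci <- match(paste(edges$child_feature[i], edges$child_term[i]), key)
    graphics::segments(xs[pi], ys[pi], xs[ci], ys[ci], col = "grey50")
  }
  graphics::text(xs, ys, nodes$label, cex = 0.8)
  invisible(x)
}

tree_to_list <- function(node) {
  # JSON has no infinities; the degenerate-variance z sentinel travels as a
  # string and is decoded by list_to_tree
  z <- if (is.numeric(node$z) && !is.na(node$z) && is.infinite(node$z))
    as.character(node$z) else node$z
  list(term = node$term, feature = node$feature, z = z,
       p_adj = node$p_adj, depth = node$depth,
       children = lapply(node$children, tree_to_list))
}

list_to_tree <- function(lst, as_root = FALSE) {
  node <- new_tree_node(lst$term %||% NA_character_,
                        lst$feature %||% NA_character_,
                        as.numeric(lst$z %||% NA_real_),
                        lst$p_adj %||% NA_real_,
                        lst$depth %||% 0L)
  node$children <- lapply(lst$children, list_to_tree)
  if (as_root) class(node) <- "causal_tree"
  node
}

#' Export a causal tree to JSON or DOT
#'
#' JSON nesting is lossless (see \code{\link{read_tree}}); the DOT digraph
#' labels each edge with its z-score for rendering with graphviz.
#'
#' @param tree a \code{causal_tree}.
#' @param path output file.
#' @param format \code{"json"} or \code{"dot"}.
#' @export
export_tree <- function(tree, path, format = c("json", "dot")) {
  format <- match.arg(format)
  if (format == "json") {
    if (!length(tree$children)) {
      writeLines("{}", path)
    } else {
      jsonlite::write_json(tree_to_list(tree), path, auto_unbox = TRUE,
                           digits = NA, na = "null")
    }
  } else {
    nodes <- tree_nodes(tree)
    lines <- c("digraph causal_tree {", "  node [shape=box];")
    if (nrow(nodes)) {
      key <- paste(nodes$feature, nodes$term)
      for (i in seq_len(nrow(nodes)))
        lines <- c(lines, sprintf('  n%d [label="%s = %s"];', i,
                                  nodes$feature[i], nodes$term[i]))
      edges <- tree_edges(tree)
      for (i in seq_len(nrow(edges))) {
        ci <- match(paste(edges$child_feature[i], edges$child_term[i]), key)
        if (is.na(edges$parent_term[i])) {
          lines <- c(lines, sprintf('  root -> n%d [label="%.2f"];', ci,
                                    edges$z[i]))
        } else {
          pi <- match(paste(edges$parent_feature[i], edges$parent_term[i]), key)
          lines <- c(lines, sprintf('  n%d -> n%d [label="%.2f"];', pi, ci,
                                    edges$z[i]))
        }
      }
    }
    writeLines(c(lines, "}"), path)
  }
  invisible(path)
}

#' Read back a JSON causal tree written by \code{\link{export_tree}}
#' @param path JSON file.
#' @return a \code{causal_tree}.
#' @export
read_tree <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(lst)) {
    root <- new_tree_node(NA_character_, NA_character_, NA_real_, NA_real_, 0L)
    class(root) <- "causal_tree"
    return(root)
  }
  list_to_tree(lst, as_root = TRUE)
}
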