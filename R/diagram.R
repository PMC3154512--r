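# Finite diagrams: a shape graph with finite sets on nodes and total maps on
# edges, plus commutativity checking by path enumeration. The sink shape
# A -> C <- B underlying every pullback is provided as a constructor.

#' Shape graph of a diagram
#'
#' A finite directed multigraph with labelled nodes and edges; diagrams
#' assign sets to nodes and maps to edges.
#'
#' @param nodes character vector of distinct node labels.
#' @param edges a data frame (or NULL for a discrete shape) with columns
#'   `name`, `from`, `to`; edge labels distinct, endpoints declared nodes.
#' @return An object of class `cat_shape`.
#' @examples
#' sink_shape()
#' @export
cat_shape <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  cs_assert(!anyDuplicated(nodes), "catsys_bad_shape", "node labels must be distinct")
  if (is.null(edges)) {
    edges <- data.frame(name = character(0), from = character(0),
                        to = character(0), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  cs_assert(all(c("name", "from", "to") %in% names(edges)), "catsys_bad_shape",
            "edges need columns name, from, to")
  cs_assert(!anyDuplicated(edges$name), "catsys_bad_shape", "edge labels must be distinct")
  bad <- setdiff(c(edges$from, edges$to), nodes)
  cs_assert(length(bad) == 0L, "catsys_bad_shape",
            sprintf("edge endpoint(s) not declared as nodes: %s",
                    paste(unique(bad), collapse = ", ")))
  structure(list(nodes = nodes, edges = edges), class = "cat_shape")
}

#' @rdname cat_shape
#' @export
sink_shape <- function() {
  cat_shape(c("left", "right", "constraint"),
            data.frame(name = c("f", "g"),
                       from = c("left", "right"),
                       to = c("constraint", "constraint"),
                       stringsAsFactors = FALSE))
}

#' @rdname cat_shape
#' @export
discrete_shape <- function(nodes) cat_shape(nodes)

shape_is_acyclic <- function(shape) {
  # Kahn peeling on the node graph.
  nodes <- shape$nodes
  edges <- shape$edges[shape$edges$from != shape$edges$to, , drop = FALSE]
  if (any(shape$edges$from == shape$edges$to)) return(FALSE)
  repeat {
    indeg <- table(factor(edges$to, levels = nodes))
    leaves <- nodes[indeg == 0]
    if (length(leaves) == 0L) break
    nodes <- setdiff(nodes, leaves)
    edges <- edges[!(edges$from %in% leaves), , drop = FALSE]
  }
  length(nodes) == 0L
}

#' Diagram over a shape
#'
#' @param shape a [cat_shape()].
#' @param objects named list of `fset`s, one per shape node.
#' @param maps named list of `fmap`s, one per shape edge; for an edge
#'   `e: n -> m` the map must have domain `objects[[n]]` and codomain
#'   `objects[[m]]`.
#' @return An object of class `cat_diagram`.
#' @export
cat_diagram <- function(shape, objects, maps = list()) {
  cs_assert(inherits(shape, "cat_shape"), "catsys_bad_diagram", "shape must be a cat_shape")
  cs_assert(setequal(names(objects), shape$nodes) &&
              length(objects) == length(shape$nodes),
            "catsys_bad_diagram", "objects must be named by exactly the shape nodes")
  cs_assert(setequal(names(maps), shape$edges$name) &&
              length(maps) == nrow(shape$edges),
            "catsys_bad_diagram", "maps must be named by exactly the shape edges")
  for (i in seq_len(nrow(shape$edges))) {
    e <- shape$edges[i, ]
    m <- maps[[e$name]]
    cs_assert(fset_equal(m$dom, objects[[e$from]]),
              "catsys_bad_diagram",
              sprintf("map on edge %s has wrong domain", e$name))
    cs_assert(fset_equal(m$cod, objects[[e$to]]),
              "catsys_bad_diagram",
              sprintf("map on edge %s has wrong codomain", e$name))
  }
  structure(list(shape = shape, objects = objects, maps = maps),
            class = "cat_diagram")
}

#' @export
print.cat_diagram <- function(x, ...) {
  cat(sprintf("diagram: %d node(s), %d edge(s)\n",
              length(x$shape$nodes), nrow(x$shape$edges)))
  for (n in x$shape$nodes) {
    cat(sprintf("  node %s: %s\n", n, format(x$objects[[n]])))
  }
  for (i in seq_len(nrow(x$shape$edges))) {
    e <- x$shape$edges[i, ]
    cat(sprintf("  edge %s: %s -> %s\n", e$name, e$from, e$to))
  }
  invisible(x)
}

# All directed edge-paths up to max_len edges, as (from, to, edge-name
# vector) records. Shapes in scope are tiny (<= ~8 nodes), so DFS suffices.
enumerate_paths <- function(shape, max_len) {
  edges <- shape$edges
  out <- list()
  dfs <- function(start, tail_node, path) {
    if (length(path) >= max_len) return(invisible())
    for (i in which(edges$from == tail_node)) {
      p <- c(path, edges$name[i])
      out[[length(out) + 1L]] <<- list(from = start, to = edges$to[i], edges = p)
      dfs(start, edges$to[i], p)
    }
  }
  for (n in shape$nodes) dfs(n, n, character(0))
  out
}

path_composite <- function(d, edge_names) {
  m <- d$maps[[edge_names[1]]]
  for (e in edge_names[-1]) m <- compose(d$maps[[e]], m)
  m
}

#' Check that a diagram commutes
#'
#' For every ordered pair of nodes, every two distinct directed paths between
#' them (at least one of length greater than one) must compose to the same
#' map. The check enumerates paths up to `max_path_len` edges; for a cyclic
#' shape a finite bound is mandatory.
#'
#' @param d a [cat_diagram()].
#' @param max_path_len maximum path length in edges (default 8, enough for
#'   every diagram this package constructs).
#' @return A list of class `catsys_report` with `ok`, `paths_compared`, and
#'   `failures` — each failure records the node pair, the two edge paths, and
#'   a witnessing element on which the composites disagree.
#' @export
check_commutative <- function(d, max_path_len = 8) {
  cs_assert(is.finite(max_path_len) || shape_is_acyclic(d$shape),
            "catsys_cyclic_shape",
            "cyclic shape requires a finite max_path_len")
  paths <- enumerate_paths(d$shape, max_path_len)
  failures <- list()
  compared <- 0L
  if (length(paths)) {
    key <- vapply(paths, function(p) paste(p$from, p$to, sep = "\r"), character(1))
    for (k in unique(key)) {
      grp <- paths[key == k]
      if (length(grp) < 2L) next
      comps <- lapply(grp, function(p) path_composite(d, p$edges))
      for (i in seq_len(length(grp) - 1L)) {
        for (j in seq.int(i + 1L, length(grp))) {
          if (length(grp[[i]]$edges) == 1L && length(grp[[j]]$edges) == 1L) next
          compared <- compared + 1L
          a <- comps[[i]]; b <- comps[[j]]
          if (!fmap_equal(a, b)) {
            diff <- names(a$assignment)[unname(a$assignment) != unname(b$assignment)]
            failures[[length(failures) + 1L]] <- list(
              from = grp[[i]]$from, to = grp[[i]]$to,
              path1 = grp[[i]]$edges, path2 = grp[[j]]$edges,
              witness = if (length(diff)) diff[1] else NA_character_,
              values = if (length(diff)) c(unname(a$assignment[diff[1]]),
                                           unname(b$assignment[diff[1]]))
                       else c(NA_character_, NA_character_))
          }
        }
      }
    }
  }
  structure(list(ok = length(failures) == 0L, paths_compared = compared,
                 failures = failures),
            class = "catsys_report")
}

#' @export
print.catsys_report <- function(x, ...) {
  cat(if (isTRUE(x$ok)) "PASS" else "FAIL", "\n")
  for (f in x$failures) {
    if (!is.null(f$path1)) {
      cat(sprintf("  paths %s vs %s disagree at %s: %s vs %s\n",
                  paste(f$path1, collapse = ";"), paste(f$path2, collapse = ";"),
                  f$witness, f$values[1], f$values[2]))
    } else {
      cat("  ", paste(vapply(f, function(v) paste(format(v), collapse = " "),
                             character(1)), collapse = " | "), "\n")
    }
  }
  invisible(x)
}

#' Cone over a diagram
#'
#' An apex set with one leg into every node object, commuting with every
#' edge map: for each edge `e: n -> m`, `map(e) . leg(n) = leg(m)`.
#' Violations raise a `catsys_not_a_cone` error.
#'
#' @param apex an `fset`.
#' @param legs named list of `fmap`s from the apex, one per diagram node.
#' @param diagram the [cat_diagram()] the cone sits over.
#' @param check validate the commutation condition (default TRUE).
#' @return An object of class `cat_cone`.
#' @export
cat_cone <- function(apex, legs, diagram, check = TRUE) {
  cs_assert(setequal(names(legs), diagram$shape$nodes),
            "catsys_not_a_cone", "cone needs one leg per diagram node")
  for (n in diagram$shape$nodes) {
    leg <- legs[[n]]
    cs_assert(fset_equal(leg$dom, apex) &&
                fset_equal(leg$cod, diagram$objects[[n]]),
              "catsys_not_a_cone",
              sprintf("leg for node %s is not a map apex -> object", n))
  }
  if (check) {
    for (i in seq_len(nrow(diagram$shape$edges))) {
      e <- diagram$shape$edges[i, ]
      lhs <- compose(diagram$maps[[e$name]], legs[[e$from]])
      cs_assert(fmap_equal(lhs, legs[[e$to]]), "catsys_not_a_cone",
                sprintf("cone does not commute over edge %s", e$name))
    }
  }
  structure(list(apex = apex, legs = legs[diagram$shape$nodes],
                 diagram = diagram),
            class = "cat_cone")
}

#' @export
print.cat_cone <- function(x, ...) {
  cat(sprintf("cone with apex %s over %d node(s)\n",
              format(x$apex), length(x$legs)))
  invisible(x)
}

#' Cocone under a diagram
#'
#' Dual of [cat_cone()]: legs run from the node objects into the apex, and
#' for each edge `e: n -> m`, `leg(m) . map(e) = leg(n)`.
#'
#' @inheritParams cat_cone
#' @return An object of class `cat_cocone`.
#' @export
cat_cocone <- function(apex, legs, diagram, check = TRUE) {
  cs_assert(setequal(names(legs), diagram$shape$nodes),
            "catsys_not_a_cone", "cocone needs one leg per diagram node")
  for (n in diagram$shape$nodes) {
    leg <- legs[[n]]
    cs_assert(fset_equal(leg$cod, apex) &&
                fset_equal(leg$dom, diagram$objects[[n]]),
              "catsys_not_a_cone",
              sprintf("leg for node %s is not a map object -> apex", n))
  }
  if (check) {
    for (i in seq_len(nrow(diagram$shape$edges))) {
      e <- diagram$shape$edges[i, ]
      lhs <- compose(legs[[e$to]], diagram$maps[[e$name]])
      cs_assert(fmap_equal(lhs, legs[[e$from]]), "catsys_not_a_cone",
                sprintf("cocone does not commute over edge %s", e$name))
    }
  }
  structure(list(apex = apex, legs = legs[diagram$shape$nodes],
                 diagram = diagram),
            class = "cat_cocone")
}
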