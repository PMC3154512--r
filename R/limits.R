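# Canonical universal constructions in finite sets: (co)products, pullbacks
# and pushouts, (co)equalizers, generic limits and colimits, the mediating
# morphism, and exhaustive verification of the universal property on probe
# apexes. Canonical cones carry a `label_of` closure mapping a family of leg
# values to the apex label, which is what makes the mediating morphism
# directly computable.

canonical_cone <- function(apex, legs, diagram, label_of) {
  cone <- cat_cone(apex, legs, diagram, check = TRUE)
  cone$label_of <- label_of
  cone
}

#' Binary product of finite sets
#'
#' The Cartesian product as a limit cone over the discrete two-node shape:
#' apex elements are pair labels `"(a,b)"` in canonical order, and the legs
#' are the coordinate projections.
#'
#' @param A,B `fset` objects.
#' @return A [cat_cone()] over the discrete shape with nodes `left`, `right`.
#' @examples
#' agents <- fset(c("John", "Mary", "Sue", "Tom"), "agents")
#' product(agents, agents)$apex
#' @export
product <- function(A, B) {
  pairs <- as.vector(outer(A$elements, B$elements, tuple_label))
  apex <- fset(pairs, name = paste0(A$name, "x", B$name))
  comp <- tuple_split(apex$elements)
  p1 <- vapply(comp, `[[`, character(1), 1L)
  p2 <- vapply(comp, `[[`, character(1), 2L)
  d <- cat_diagram(discrete_shape(c("left", "right")),
                   list(left = A, right = B))
  legs <- list(
    left = fmap(apex, A, structure(p1, names = apex$elements), name = "p1"),
    right = fmap(apex, B, structure(p2, names = apex$elements), name = "p2")
  )
  canonical_cone(apex, legs, d,
                 label_of = function(v) tuple_label(v[["left"]], v[["right"]]))
}

#' Pullback of two maps with a common codomain
#'
#' The constrained product: the apex contains exactly the pairs `"(a,b)"`
#' with `f(a) = g(b)`, with coordinate projections as legs. The result is a
#' limit cone over the sink shape `left -> constraint <- right`, and the full
#' sink diagram together with the legs commutes by construction.
#'
#' @param f,g `fmap` objects with equal codomains.
#' @return A [cat_cone()] over the sink diagram of `f` and `g`.
#' @export
pullback <- function(f, g) {
  cs_assert(fset_equal(f$cod, g$cod), "catsys_codomain_mismatch",
            sprintf("pullback needs a common codomain: %s vs %s",
                    format(f$cod), format(g$cod)))
  A <- f$dom; B <- g$dom
  keep_a <- rep(A$elements, each = fset_size(B))
  keep_b <- rep(B$elements, times = fset_size(A))
  agree <- unname(f$assignment[keep_a]) == unname(g$assignment[keep_b])
  pairs <- tuple_label(keep_a[agree], keep_b[agree])
  apex <- fset(pairs, name = paste0(A$name, "x_", f$cod$name, "_", B$name))
  comp <- tuple_split(apex$elements)
  p1 <- vapply(comp, `[[`, character(1), 1L)
  p2 <- vapply(comp, `[[`, character(1), 2L)
  d <- cat_diagram(sink_shape(),
                   list(left = A, right = B, constraint = f$cod),
                   list(f = f, g = g))
  leg_left <- fmap(apex, A, structure(p1, names = apex$elements), name = "p1")
  leg_right <- fmap(apex, B, structure(p2, names = apex$elements), name = "p2")
  legs <- list(left = leg_left, right = leg_right,
               constraint = compose(f, leg_left, name = "p0"))
  canonical_cone(apex, legs, d,
                 label_of = function(v) tuple_label(v[["left"]], v[["right"]]))
}

parallel_shape <- function() {
  cat_shape(c("dom", "cod"),
            data.frame(name = c("f", "g"), from = c("dom", "dom"),
                       to = c("cod", "cod"), stringsAsFactors = FALSE))
}

#' Equalizer of two parallel maps
#'
#' The subset `{x : f(x) = g(x)}` of the common domain, with the inclusion
#' as leg; a limit cone over the parallel-pair shape.
#'
#' @param f,g parallel `fmap`s (same domain, same codomain).
#' @return A [cat_cone()] with apex the agreement subset.
#' @export
equalizer <- function(f, g) {
  cs_assert(fset_equal(f$dom, g$dom) && fset_equal(f$cod, g$cod),
            "catsys_not_parallel", "equalizer needs parallel maps")
  keep <- f$dom$elements[unname(f$assignment) == unname(g$assignment)]
  apex <- fset(keep, name = paste0("Eq_", f$name, "_", g$name))
  d <- cat_diagram(parallel_shape(), list(dom = f$dom, cod = f$cod),
                   list(f = f, g = g))
  incl <- fmap(apex, f$dom, structure(keep, names = keep), name = "incl")
  legs <- list(dom = incl, cod = compose(f, incl))
  canonical_cone(apex, legs, d, label_of = function(v) v[["dom"]])
}

# --- colimit side ------------------------------------------------------------

# Union-find with class labels = lexicographically least member.
uf_partition <- function(elements, pair_a, pair_b) {
  parent <- seq_along(elements)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- function(x) match(x, elements)
  ia <- idx(pair_a); ib <- idx(pair_b)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_along(elements), find, integer(1))
  label <- vapply(split(elements, root), function(m) canon_sort(m)[1], character(1))
  class_of <- label[as.character(root)]
  names(class_of) <- elements
  class_of
}

#' Binary coproduct (tagged disjoint union)
#'
#' The apex is the disjoint union of the two sets with elements tagged by
#' their side (`"left:x"`, `"right:y"`); legs are the tagged injections.
#'
#' @param A,B `fset` objects.
#' @return A [cat_cocone()] over the discrete two-node shape.
#' @export
coproduct <- function(A, B) {
  la <- paste0("left:", A$elements)
  rb <- paste0("right:", B$elements)
  apex <- fset(c(la, rb), name = paste0(A$name, "+", B$name))
  d <- cat_diagram(discrete_shape(c("left", "right")),
                   list(left = A, right = B))
  legs <- list(
    left = fmap(A, apex, structure(la, names = A$elements), name = "inl"),
    right = fmap(B, apex, structure(rb, names = B$elements), name = "inr")
  )
  cat_cocone(apex, legs, d)
}

#' Coequalizer of two parallel maps
#'
#' The quotient of the codomain by the equivalence relation generated by
#' `f(x) ~ g(x)`. Each equivalence class is labelled by its
#' lexicographically least member, and the class leg sends every codomain
#' element to its class label.
#'
#' @param f,g parallel `fmap`s.
#' @return A [cat_cocone()] over the parallel-pair shape; the extra field
#'   `classes` lists the members of each class.
#' @export
coequalizer <- function(f, g) {
  cs_assert(fset_equal(f$dom, g$dom) && fset_equal(f$cod, g$cod),
            "catsys_not_parallel", "coequalizer needs parallel maps")
  class_of <- uf_partition(f$cod$elements,
                           unname(f$assignment), unname(g$assignment))
  apex <- fset(unique(unname(class_of)), name = paste0(f$cod$name, "/~"))
  d <- cat_diagram(parallel_shape(), list(dom = f$dom, cod = f$cod),
                   list(f = f, g = g))
  q <- fmap(f$cod, apex, class_of, name = "q")
  cocone <- cat_cocone(apex, legs = list(dom = compose(q, f), cod = q), d)
  cocone$classes <- split(names(class_of), unname(class_of))
  cocone
}

span_shape <- function() {
  cat_shape(c("center", "left", "right"),
            data.frame(name = c("f", "g"), from = c("center", "center"),
                       to = c("left", "right"), stringsAsFactors = FALSE))
}

#' Pushout of two maps with a common domain
#'
#' The quotient of the tagged disjoint union of the two codomains by the
#' equivalence generated by `f(z) ~ g(z)`; class labels are the
#' lexicographically least tagged member.
#'
#' @param f,g `fmap`s with equal domains.
#' @return A [cat_cocone()] over the span shape, with a `classes` field.
#' @export
pushout <- function(f, g) {
  cs_assert(fset_equal(f$dom, g$dom), "catsys_domain_mismatch",
            "pushout needs a common domain")
  la <- paste0("left:", f$cod$elements)
  rb <- paste0("right:", g$cod$elements)
  universe <- c(la, rb)
  class_of <- uf_partition(universe,
                           paste0("left:", unname(f$assignment)),
                           paste0("right:", unname(g$assignment)))
  apex <- fset(unique(unname(class_of)),
               name = paste0(f$cod$name, "+_", f$dom$name, "_", g$cod$name))
  d <- cat_diagram(span_shape(),
                   list(center = f$dom, left = f$cod, right = g$cod),
                   list(f = f, g = g))
  leg_left <- fmap(f$cod, apex,
                   structure(unname(class_of[paste0("left:", f$cod$elements)]),
                             names = f$cod$elements), name = "q1")
  leg_right <- fmap(g$cod, apex,
                    structure(unname(class_of[paste0("right:", g$cod$elements)]),
                              names = g$cod$elements), name = "q2")
  cocone <- cat_cocone(apex,
                       legs = list(center = compose(leg_left, f),
                                   left = leg_left, right = leg_right), d)
  cocone$classes <- split(names(class_of), unname(class_of))
  cocone
}

# --- generic limit / colimit -------------------------------------------------

#' Limit of a finite diagram
#'
#' The apex consists of all node-indexed families `(x_n)` compatible with
#' every edge map, encoded as tuple labels with components in canonical
#' (lexicographic) node order. The empty diagram yields the terminal object,
#' a singleton `"()"`; a discrete two-node diagram yields the product; the
#' sink diagram yields the pullback (up to the choice of tuple components).
#'
#' @param d a [cat_diagram()].
#' @param cap refuse to build more than `cap` candidate families.
#' @return A [cat_cone()] whose legs are the family projections.
#' @export
limit <- function(d, cap = 1e6) {
  nodes <- canon_sort(d$shape$nodes)
  if (length(nodes) == 0L) {
    apex <- fset("()", name = "1")
    return(canonical_cone(apex, legs = list(), d,
                          label_of = function(v) "()"))
  }
  sizes <- vapply(nodes, function(n) fset_size(d$objects[[n]]), numeric(1))
  total <- prod(sizes)
  cs_assert(total <= cap, "catsys_cap_exceeded",
            sprintf("limit candidate count %s exceeds cap %s",
                    format(total, scientific = FALSE),
                    format(cap, scientific = FALSE)))
  if (total == 0) {
    grid <- matrix(character(0), nrow = 0, ncol = length(nodes),
                   dimnames = list(NULL, nodes))
  } else {
    g <- do.call(expand.grid, c(lapply(nodes, function(n) d$objects[[n]]$elements),
                                list(stringsAsFactors = FALSE)))
    grid <- as.matrix(g)
    colnames(grid) <- nodes
  }
  for (i in seq_len(nrow(d$shape$edges))) {
    e <- d$shape$edges[i, ]
    m <- d$maps[[e$name]]
    keep <- unname(m$assignment[grid[, e$from]]) == grid[, e$to]
    grid <- grid[keep, , drop = FALSE]
  }
  labels <- if (nrow(grid)) do.call(tuple_label, split(grid, col(grid))) else character(0)
  apex <- fset(labels, name = "Lim")
  ord <- match(apex$elements, labels)
  legs <- lapply(nodes, function(n) {
    fmap(apex, d$objects[[n]],
         structure(grid[ord, n], names = apex$elements),
         name = paste0("pr_", n))
  })
  names(legs) <- nodes
  canonical_cone(apex, legs, d,
                 label_of = function(v) do.call(tuple_label, as.list(v[nodes])))
}

#' Colimit of a finite diagram
#'
#' The quotient of the node-tagged disjoint union of all node objects by the
#' equivalence generated by `x ~ map(e)(x)` across every edge; class labels
#' are the lexicographically least tagged member.
#'
#' @param d a [cat_diagram()].
#' @return A [cat_cocone()] with a `classes` field.
#' @export
colimit <- function(d) {
  nodes <- canon_sort(d$shape$nodes)
  tagged <- unlist(lapply(nodes, function(n)
    paste0(n, ":", d$objects[[n]]$elements)))
  pa <- character(0); pb <- character(0)
  for (i in seq_len(nrow(d$shape$edges))) {
    e <- d$shape$edges[i, ]
    m <- d$maps[[e$name]]
    pa <- c(pa, paste0(e$from, ":", names(m$assignment)))
    pb <- c(pb, paste0(e$to, ":", unname(m$assignment)))
  }
  if (length(tagged) == 0L) {
    apex <- fset(character(0), name = "0")
    legs <- lapply(nodes, function(n)
      fmap(d$objects[[n]], apex, character(0), name = paste0("in_", n)))
    names(legs) <- nodes
    cocone <- cat_cocone(apex, legs, d)
    cocone$classes <- list()
    return(cocone)
  }
  class_of <- uf_partition(tagged, pa, pb)
  apex <- fset(unique(unname(class_of)), name = "Colim")
  legs <- lapply(nodes, function(n) {
    els <- d$objects[[n]]$elements
    fmap(d$objects[[n]], apex,
         structure(unname(class_of[paste0(n, ":", els)]), names = els),
         name = paste0("in_", n))
  })
  names(legs) <- nodes
  cocone <- cat_cocone(apex, legs, d)
  cocone$classes <- split(names(class_of), unname(class_of))
  cocone
}

# --- mediating morphism & universal-property verification --------------------

# Validate that `legs` over `diagram` commute; returns TRUE/FALSE.
cone_commutes <- function(apex, legs, diagram) {
  for (i in seq_len(nrow(diagram$shape$edges))) {
    e <- diagram$shape$edges[i, ]
    lhs <- compose(diagram$maps[[e$name]], legs[[e$from]])
    if (!fmap_equal(lhs, legs[[e$to]])) return(FALSE)
  }
  TRUE
}

#' Mediating morphism into a canonical limit cone
#'
#' For a cone `c` over the same diagram as the canonical limit cone `u`,
#' returns the unique map `m : apex(c) -> apex(u)` with
#' `legs(u)[n] . m = legs(c)[n]` for every node. For the canonical cones
#' built by this package the map is computed directly (each apex element is
#' the tuple of its leg values); otherwise it is found by exhaustive search
#' over [enumerate_maps()]. A `catsys_no_factorization` error is raised when
#' `c` does not commute (it is not actually a cone) or no factorization
#' exists.
#'
#' @param c a [cat_cone()] (possibly built with `check = FALSE`).
#' @param u the canonical limit cone over the same diagram.
#' @param cap enumeration cap for the search fallback.
#' @return The mediating `fmap`.
#' @export
mediating_morphism <- function(c, u, cap = 1e6) {
  cs_assert(setequal(names(c$legs), names(u$legs)), "catsys_no_factorization",
            "cones are not over the same diagram")
  if (!cone_commutes(c$apex, c$legs, u$diagram)) {
    cs_stop("catsys_no_factorization", "c is not a cone: its legs do not commute")
  }
  nodes <- names(u$legs)
  if (!is.null(u$label_of)) {
    asg <- vapply(c$apex$elements, function(x) {
      v <- vapply(nodes, function(n) unname(c$legs[[n]]$assignment[[x]]),
                  character(1))
      names(v) <- nodes
      u$label_of(v)
    }, character(1))
    bad <- setdiff(unname(asg), u$apex$elements)
    cs_assert(length(bad) == 0L, "catsys_no_factorization",
              "cone legs select families outside the limit apex")
    m <- fmap(c$apex, u$apex, asg, name = "u")
  } else {
    cands <- enumerate_maps(c$apex, u$apex, cap = cap)
    ok <- Filter(function(h) {
      all(vapply(nodes, function(n)
        fmap_equal(compose(u$legs[[n]], h), c$legs[[n]]), logical(1)))
    }, cands)
    cs_assert(length(ok) >= 1L, "catsys_no_factorization", "no factorization exists")
    cs_assert(length(ok) == 1L, "catsys_not_universal",
              sprintf("%d distinct factorizations exist", length(ok)))
    m <- ok[[1]]
  }
  for (n in nodes) {
    cs_assert(fmap_equal(compose(u$legs[[n]], m), c$legs[[n]]),
              "catsys_no_factorization",
              sprintf("factorization fails at node %s", n))
  }
  m
}

#' Default probe apexes for universal-property checks
#'
#' All finite sets of sizes 0, 1 and 2 over a fixed two-letter alphabet.
#' Full quantification over all objects is impossible; probes of size up to
#' two already separate existence failures (size 1) from uniqueness failures
#' (size 2) for every construction in scope.
#'
#' @return A list of `fset`s of sizes 0, 1, 2.
#' @export
default_probes <- function() {
  list(fset(character(0), "X0"), fset("p", "X1"), fset(c("p", "q"), "X2"))
}

# All cones over d with apex X, returned as a list of leg-index vectors into
# per-node map tables. Vectorized: per-node maps are rows of a character
# matrix; edge constraints filter an index grid by key comparison.
enumerate_cones <- function(d, X, cap) {
  nodes <- canon_sort(d$shape$nodes)
  nX <- fset_size(X)
  tables <- lapply(nodes, function(n) {
    B <- d$objects[[n]]
    nB <- fset_size(B)
    count <- if (nX == 0L) 1 else nB^nX
    cs_assert(count <= cap, "catsys_cap_exceeded",
              sprintf("per-node map count %s exceeds cap", format(count)))
    if (nX == 0L) {
      matrix(character(0), nrow = 1, ncol = 0)
    } else if (nB == 0L) {
      matrix(character(0), nrow = 0, ncol = nX)
    } else {
      g <- do.call(expand.grid, c(rep(list(B$elements), nX),
                                  list(stringsAsFactors = FALSE)))
      mat <- as.matrix(g)
      colnames(mat) <- X$elements
      mat
    }
  })
  names(tables) <- nodes
  total <- prod(vapply(tables, nrow, numeric(1)))
  cs_assert(total <= cap, "catsys_cap_exceeded",
            sprintf("cone candidate count %s exceeds cap %s",
                    format(total, scientific = FALSE),
                    format(cap, scientific = FALSE)))
  if (total == 0) {
    return(list(tables = tables,
                grid = matrix(integer(0), nrow = 0, ncol = length(nodes),
                              dimnames = list(NULL, nodes))))
  }
  g <- do.call(expand.grid, lapply(tables, function(tb) seq_len(nrow(tb))))
  grid <- as.matrix(g)
  colnames(grid) <- nodes
  row_keys <- function(mat) {
    if (ncol(mat) == 0L) rep("", nrow(mat))
    else do.call(paste, c(split(mat, col(mat)), list(sep = "\r")))
  }
  keys <- lapply(tables, row_keys)
  for (i in seq_len(nrow(d$shape$edges))) {
    e <- d$shape$edges[i, ]
    m <- d$maps[[e$name]]
    tb <- tables[[e$from]]
    mapped <- matrix(unname(m$assignment[tb]), nrow = nrow(tb))
    keep <- row_keys(mapped)[grid[, e$from]] == keys[[e$to]][grid[, e$to]]
    grid <- grid[keep, , drop = FALSE]
  }
  list(tables = tables, grid = grid)
}

#' Exhaustively verify the universal property of a cone
#'
#' For every probe apex `X` and every cone over the diagram with apex `X`
#' (enumerated exhaustively), there must exist exactly one mediating map into
#' `u`. This is the executable reading of a limit: every competitor factors
#' through the universal cone, uniquely.
#'
#' @param u the candidate limit [cat_cone()].
#' @param d the diagram (defaults to the diagram stored in `u`).
#' @param probe_apexes list of probe `fset`s; defaults to [default_probes()].
#' @param cap enumeration cap guarding the exhaustive searches.
#' @return A `catsys_report` with `ok`, `cones_tested`, and `failures` (each
#'   naming the probe, the leg images, and the number of factorizations
#'   found, for every cone with 0 or at least 2).
#' @export
verify_universal <- function(u, d = u$diagram, probe_apexes = default_probes(),
                             cap = 1e6) {
  nodes <- canon_sort(d$shape$nodes)
  failures <- list()
  tested <- 0L
  for (X in probe_apexes) {
    cones <- enumerate_cones(d, X, cap)
    grid <- cones$grid
    tables <- cones$tables
    nX <- fset_size(X)
    # candidate mediating maps X -> apex(u), as a matrix of images
    napex <- fset_size(u$apex)
    hcount <- if (nX == 0L) 1 else napex^nX
    cs_assert(hcount <= cap, "catsys_cap_exceeded",
              sprintf("mediating candidate count %s exceeds cap", format(hcount)))
    H <- if (nX == 0L) {
      matrix(character(0), nrow = 1, ncol = 0)
    } else if (napex == 0L) {
      matrix(character(0), nrow = 0, ncol = nX)
    } else {
      g <- do.call(expand.grid, c(rep(list(u$apex$elements), nX),
                                  list(stringsAsFactors = FALSE)))
      as.matrix(g)
    }
    row_keys <- function(mat) {
      if (ncol(mat) == 0L) rep("", nrow(mat))
      else do.call(paste, c(split(mat, col(mat)), list(sep = "\r")))
    }
    # key of (leg_u[n] . h) for every candidate h, per node
    hkeys <- lapply(nodes, function(n) {
      img <- matrix(unname(u$legs[[n]]$assignment[H]), nrow = nrow(H))
      row_keys(img)
    })
    names(hkeys) <- nodes
    conekeys <- lapply(nodes, function(n) row_keys(tables[[n]]))
    names(conekeys) <- nodes
    for (r in seq_len(nrow(grid))) {
      tested <- tested + 1L
      match_all <- rep(TRUE, nrow(H))
      for (n in nodes) {
        match_all <- match_all & (hkeys[[n]] == conekeys[[n]][grid[r, n]])
      }
      nfac <- sum(match_all)
      if (nfac != 1L) {
        legs_desc <- vapply(nodes, function(n)
          paste0(n, "=[", paste(tables[[n]][grid[r, n], ], collapse = ","), "]"),
          character(1))
        failures[[length(failures) + 1L]] <- list(
          probe = X$name, cone = paste(legs_desc, collapse = " "),
          factorizations = nfac)
      }
    }
  }
  structure(list(ok = length(failures) == 0L, cones_tested = tested,
                 failures = failures),
            class = "catsys_report")
}

#' Canonical isomorphism between two universal cones
#'
#' Any two cones over the same diagram that both satisfy the universal
#' property are related by a unique isomorphism: the mediating morphisms in
#' both directions, whose composites are forced to be the identities.
#'
#' @param u1,u2 two limit cones over the same diagram (both must carry the
#'   universal property; this is not re-verified here).
#' @param cap enumeration cap for the mediating-map searches.
#' @return A list with `iso` (u1 -> u2), `inverse` (u2 -> u1), and `ok`
#'   (TRUE when both composites are identities).
#' @export
universal_iso <- function(u1, u2, cap = 1e6) {
  m12 <- mediating_morphism(u1, u2, cap = cap)
  m21 <- mediating_morphism(u2, u1, cap = cap)
  ok <- fmap_equal(compose(m21, m12), id_map(u1$apex)) &&
    fmap_equal(compose(m12, m21), id_map(u2$apex))
  list(iso = m12, inverse = m21, ok = ok)
}
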