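# The cognitive-domain layer: a relation over a lexicon or formal domain is
# declared as a DomainSpec in one of five construction styles, realized as a
# pullback (or product / quotient) with named role projections, and then
# exercised: role inference, membership with diagnostic reasons, quotient
# structure, an architecture audit for (quasi-)systematicity, and the
# block-matrix rendering of a shared-constraint relation.

DOMAIN_STYLES <- c("product", "shared_constraint", "refined_triple",
                   "characteristic", "quotient")

#' Declare a cognitive domain
#'
#' A `domain_spec` names the finite sets, maps, role names, and construction
#' style from which [realize()] builds the relation. Set keys are
#' structural and reserved per style (`left`, `right`, `constraint`,
#' `left_pairs`, `right_pairs`, `base`); display names live on the `fset`s
#' themselves. Roles attach domain vocabulary (e.g. `progenitor`,
#' `offspring`) to sides.
#'
#' Style requirements:
#' \describe{
#'   \item{product}{sets `left`, `right`; no maps. The full product.}
#'   \item{shared_constraint}{sets `left`, `right`, `constraint`; maps
#'     `left_attr : left -> constraint` and
#'     `right_attr : right -> constraint`. The pullback of the two
#'     attribute maps.}
#'   \item{refined_triple}{sets `left_pairs` (elements `"(x,c)"`),
#'     `right_pairs` (elements `"(c,y)"`), `constraint`; maps `left_attr`,
#'     `right_attr` projecting the shared constraint coordinate. The
#'     pullback, re-encoded as triples `"(x,c,y)"` with the constraint in
#'     the middle.}
#'   \item{characteristic}{sets `left`, `right` and an explicit `relation`
#'     pair list. The pullback of the characteristic map
#'     `chi : left x right -> {false,true}` along the truth inclusion
#'     `true : 1 -> {false,true}` — the subobject-classifier presentation
#'     that works for an arbitrary relation.}
#'   \item{quotient}{set `base`; map `classifier`. The kernel-pair
#'     coequalizer of the classifier (see [quotient()]).}
#' }
#'
#' @param name display name of the domain.
#' @param style one of `r paste(DOMAIN_STYLES, collapse = ", ")`.
#' @param sets named list of `fset`s, keyed as above.
#' @param maps named list of `fmap`s, keyed as above.
#' @param roles named character vector: role name to side (`left`, `right`,
#'   `constraint`).
#' @param relation for the characteristic style: list of 2-element character
#'   vectors, the pairs of the relation.
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(name, style, sets, maps = list(), roles = character(0),
                        relation = NULL) {
  cs_assert(style %in% DOMAIN_STYLES, "catsys_malformed_spec",
            sprintf("unknown style '%s' (expected one of %s)", style,
                    paste(DOMAIN_STYLES, collapse = ", ")))
  need_sets <- switch(style,
    product = c("left", "right"),
    shared_constraint = c("left", "right", "constraint"),
    refined_triple = c("left_pairs", "right_pairs", "constraint"),
    characteristic = c("left", "right"),
    quotient = "base")
  missing <- setdiff(need_sets, names(sets))
  cs_assert(length(missing) == 0L, "catsys_malformed_spec",
            sprintf("style %s requires set(s): %s", style,
                    paste(missing, collapse = ", ")))
  for (s in sets) cs_assert(is_fset(s), "catsys_malformed_spec",
                            "all sets must be fset objects")
  for (m in maps) cs_assert(is_fmap(m), "catsys_malformed_spec",
                            "all maps must be fmap objects")
  roles <- unlist(roles)
  if (is.null(roles) || length(roles) == 0L) {
    roles <- structure(character(0), names = character(0))
  }
  storage.mode(roles) <- "character"
  bad_side <- setdiff(unname(roles), c("left", "right", "constraint"))
  cs_assert(length(bad_side) == 0L, "catsys_malformed_spec",
            sprintf("unknown role side(s): %s", paste(bad_side, collapse = ", ")))
  if (style %in% c("shared_constraint", "refined_triple")) {
    for (mn in c("left_attr", "right_attr")) {
      cs_assert(mn %in% names(maps), "catsys_malformed_spec",
                sprintf("style %s requires map '%s'", style, mn))
    }
    src <- if (style == "shared_constraint") c("left", "right") else
      c("left_pairs", "right_pairs")
    cs_assert(fset_equal(maps$left_attr$dom, sets[[src[1]]]) &&
                fset_equal(maps$left_attr$cod, sets$constraint),
              "catsys_malformed_spec",
              sprintf("left_attr must map %s into constraint", src[1]))
    cs_assert(fset_equal(maps$right_attr$dom, sets[[src[2]]]) &&
                fset_equal(maps$right_attr$cod, sets$constraint),
              "catsys_malformed_spec",
              sprintf("right_attr must map %s into constraint", src[2]))
  }
  if (style == "refined_triple") {
    # pair-set elements must be well-formed pairs sharing the constraint coord
    for (x in sets$left_pairs$elements) {
      comp <- tuple_split(x)[[1]]
      cs_assert(length(comp) == 2L, "catsys_malformed_spec",
                sprintf("left_pairs element %s is not a pair", x))
      cs_assert(unname(maps$left_attr$assignment[[x]]) == comp[2],
                "catsys_malformed_spec",
                sprintf("left_attr must project the second coordinate of %s", x))
    }
    for (x in sets$right_pairs$elements) {
      comp <- tuple_split(x)[[1]]
      cs_assert(length(comp) == 2L, "catsys_malformed_spec",
                sprintf("right_pairs element %s is not a pair", x))
      cs_assert(unname(maps$right_attr$assignment[[x]]) == comp[1],
                "catsys_malformed_spec",
                sprintf("right_attr must project the first coordinate of %s", x))
    }
  }
  if (style == "characteristic") {
    cs_assert(is.list(relation), "catsys_malformed_spec",
              "characteristic style requires an explicit relation pair list")
    for (pr in relation) {
      cs_assert(length(pr) == 2L, "catsys_malformed_spec",
                "relation entries must be pairs")
      cs_assert(pr[1] %in% sets$left$elements, "catsys_malformed_spec",
                sprintf("relation component %s not in left set", pr[1]))
      cs_assert(pr[2] %in% sets$right$elements, "catsys_malformed_spec",
                sprintf("relation component %s not in right set", pr[2]))
    }
  }
  if (style == "quotient") {
    cs_assert("classifier" %in% names(maps), "catsys_malformed_spec",
              "quotient style requires map 'classifier'")
    cs_assert(fset_equal(maps$classifier$dom, sets$base),
              "catsys_malformed_spec", "classifier must be total on base")
  }
  structure(list(name = name, style = style, sets = sets, maps = maps,
                 roles = roles, relation = relation),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf("domain_spec '%s' (style %s)\n", x$name, x$style))
  for (k in names(x$sets)) cat(sprintf("  set %s: %s\n", k, format(x$sets[[k]])))
  for (k in names(x$maps)) cat(sprintf("  map %s: %s -> %s\n", k,
                                       format(x$maps[[k]]$dom),
                                       format(x$maps[[k]]$cod)))
  if (length(x$roles)) {
    cat("  roles:", paste(names(x$roles), unname(x$roles), sep = "=",
                          collapse = ", "), "\n")
  }
  if (!is.null(x$relation)) {
    cat(sprintf("  relation: %d pair(s)\n", length(x$relation)))
  }
  invisible(x)
}

role_of_side <- function(spec, side) {
  r <- names(spec$roles)[unname(spec$roles) == side]
  if (length(r)) r[1] else NA_character_
}

#' Realize a cognitive domain as a verified construction
#'
#' Builds the universal construction the style prescribes, together with the
#' witness diagram and the role projections. Product and pullback styles
#' return a `realized_relation`: the apex holds exactly the licensed
#' instances, the projections recover role fillers, and the stored pullback
#' cone is what [verify_universal()] and [check_commutative()] audit. The
#' quotient style returns a [quotient()] structure.
#'
#' @param spec a [domain_spec()].
#' @return A `realized_relation` (or `quotient_structure` for the quotient
#'   style).
#' @export
realize <- function(spec) {
  cs_assert(inherits(spec, "domain_spec"), "catsys_malformed_spec",
            "realize expects a domain_spec")
  switch(spec$style,
    product = realize_product(spec),
    shared_constraint = realize_shared(spec),
    refined_triple = realize_triple(spec),
    characteristic = realize_characteristic(spec),
    quotient = quotient(spec$sets$base, spec$maps$classifier, spec = spec))
}

new_realized <- function(spec, apex, projections, cone) {
  structure(list(spec = spec, apex = apex, projections = projections,
                 cone = cone, diagram = cone$diagram),
            class = "realized_relation")
}

#' @export
print.realized_relation <- function(x, ...) {
  cat(sprintf("realized relation '%s' (style %s): %d instance(s)\n",
              x$spec$name, x$spec$style, fset_size(x$apex)))
  cat("  apex: {", paste(x$apex$elements, collapse = ", "), "}\n")
  cat("  roles:", paste(names(x$projections), collapse = ", "), "\n")
  invisible(x)
}

realize_product <- function(spec) {
  cone <- product(spec$sets$left, spec$sets$right)
  projections <- list()
  rl <- role_of_side(spec, "left"); rr <- role_of_side(spec, "right")
  if (!is.na(rl)) projections[[rl]] <- cone$legs$left
  if (!is.na(rr)) projections[[rr]] <- cone$legs$right
  new_realized(spec, cone$apex, projections, cone)
}

realize_shared <- function(spec) {
  cone <- pullback(spec$maps$left_attr, spec$maps$right_attr)
  projections <- list()
  rl <- role_of_side(spec, "left"); rr <- role_of_side(spec, "right")
  rc <- role_of_side(spec, "constraint")
  if (!is.na(rl)) projections[[rl]] <- cone$legs$left
  if (!is.na(rr)) projections[[rr]] <- cone$legs$right
  if (!is.na(rc)) projections[[rc]] <- cone$legs$constraint
  new_realized(spec, cone$apex, projections, cone)
}

realize_triple <- function(spec) {
  cone <- pullback(spec$maps$left_attr, spec$maps$right_attr)
  # apex elements are pairs of pairs ((x,c),(c,y)); re-encode as (x,c,y)
  comp <- tuple_split(cone$apex$elements)
  triples <- vapply(comp, function(pr) {
    lc <- tuple_split(pr[1])[[1]]
    rc <- tuple_split(pr[2])[[1]]
    tuple_label(lc[1], lc[2], rc[2])
  }, character(1))
  apex <- fset(triples, name = paste0(spec$name, "_triples"))
  parts <- tuple_split(apex$elements)
  proj <- function(i, cod, nm) {
    fmap(apex, cod,
         structure(vapply(parts, `[[`, character(1), i), names = apex$elements),
         name = nm)
  }
  first <- vapply(tuple_split(spec$sets$left_pairs$elements), `[[`, character(1), 1L)
  third <- vapply(tuple_split(spec$sets$right_pairs$elements), `[[`, character(1), 2L)
  projections <- list()
  rl <- role_of_side(spec, "left"); rr <- role_of_side(spec, "right")
  rc <- role_of_side(spec, "constraint")
  if (!is.na(rl)) projections[[rl]] <- proj(1L, fset(first, "firsts"), rl)
  if (!is.na(rc)) projections[[rc]] <- proj(2L, spec$sets$constraint, rc)
  if (!is.na(rr)) projections[[rr]] <- proj(3L, fset(third, "thirds"), rr)
  r <- new_realized(spec, apex, projections, cone)
  # bijection triple apex <-> pullback pair-of-pairs apex
  r$presentation <- fmap(apex, cone$apex,
                         structure(cone$apex$elements[match(apex$elements, triples)],
                                   names = apex$elements),
                         name = "present")
  r
}

realize_characteristic <- function(spec) {
  prod_cone <- product(spec$sets$left, spec$sets$right)
  A <- prod_cone$apex
  omega <- fset(c("false", "true"), "Omega")
  one <- fset("*", "1")
  rel_labels <- vapply(spec$relation, function(pr) tuple_label(pr[1], pr[2]),
                       character(1))
  chi <- fmap(A, omega,
              structure(ifelse(A$elements %in% rel_labels, "true", "false"),
                        names = A$elements), name = "chi")
  truth <- fmap(one, omega, c(`*` = "true"), name = "true")
  cone <- pullback(chi, truth)
  # apex elements are ((a,b),*); present them as the bare pairs (a,b)
  pairs <- vapply(tuple_split(cone$apex$elements), `[[`, character(1), 1L)
  apex <- fset(pairs, name = paste0(spec$name, "_rel"))
  parts <- tuple_split(apex$elements)
  projections <- list()
  rl <- role_of_side(spec, "left"); rr <- role_of_side(spec, "right")
  if (!is.na(rl)) {
    projections[[rl]] <- fmap(apex, spec$sets$left,
                              structure(vapply(parts, `[[`, character(1), 1L),
                                        names = apex$elements), name = rl)
  }
  if (!is.na(rr)) {
    projections[[rr]] <- fmap(apex, spec$sets$right,
                              structure(vapply(parts, `[[`, character(1), 2L),
                                        names = apex$elements), name = rr)
  }
  r <- new_realized(spec, apex, projections, cone)
  r$chi <- chi
  r$truth <- truth
  r
}

#' Infer a role filler from a realized relation
#'
#' Selects the unique apex instance matching the selector (equality
#' constraints on role values) and applies the requested role projection —
#' e.g. selecting the square-relation instance with root 4 and projecting
#' the square role yields 16.
#'
#' @param r a `realized_relation`.
#' @param role role name to project.
#' @param selector named character vector of `role = value` constraints.
#' @return The inferred element label.
#' @export
infer <- function(r, role, selector) {
  cs_assert(role %in% names(r$projections), "catsys_no_match",
            sprintf("unknown role '%s' (have: %s)", role,
                    paste(names(r$projections), collapse = ", ")))
  cs_assert(all(names(selector) %in% names(r$projections)), "catsys_no_match",
            "selector constrains unknown role(s)")
  hits <- r$apex$elements
  for (sr in names(selector)) {
    vals <- unname(r$projections[[sr]]$assignment[hits])
    hits <- hits[vals == selector[[sr]]]
  }
  cs_assert(length(hits) > 0L, "catsys_no_match",
            sprintf("no instance matches selector (%s)",
                    paste(names(selector), selector, sep = "=", collapse = ", ")))
  cs_assert(length(hits) == 1L, "catsys_ambiguous_match",
            sprintf("%d instances match selector", length(hits)))
  unname(r$projections[[role]]$assignment[[hits]])
}

#' Membership test with diagnostic reason
#'
#' Decides whether a candidate instance is licensed by the realized
#' relation, and when it is not, explains why: a `role_set` violation means
#' a component sits on the wrong side (e.g. an offspring offered as a
#' progenitor); a `constraint` violation means all components are on their
#' proper sides but the shared-attribute (commutativity) condition fails
#' (e.g. a stallion paired with a steer). Components drawn from none of the
#' domain's sets raise a `catsys_unknown_component` error.
#'
#' @param r a `realized_relation`.
#' @param candidate character vector of components in role order (left
#'   \[, constraint\], right), or a single encoded tuple label.
#' @return A list with `member` (logical), `reason` (`"member"`,
#'   `"role_set"`, or `"constraint"`), and `detail`.
#' @export
membership <- function(r, candidate) {
  spec <- r$spec
  if (length(candidate) == 1L && grepl("^\\(", candidate)) {
    candidate <- tuple_split(candidate)[[1]]
  }
  side_sets <- switch(spec$style,
    product = list(spec$sets$left, spec$sets$right),
    shared_constraint = list(spec$sets$left, spec$sets$right),
    characteristic = list(spec$sets$left, spec$sets$right),
    refined_triple = {
      firsts <- vapply(tuple_split(spec$sets$left_pairs$elements), `[[`,
                       character(1), 1L)
      thirds <- vapply(tuple_split(spec$sets$right_pairs$elements), `[[`,
                       character(1), 2L)
      list(fset(firsts), spec$sets$constraint, fset(thirds))
    },
    cs_stop("catsys_wrong_style", "membership applies to relational styles"))
  cs_assert(length(candidate) == length(side_sets), "catsys_unknown_component",
            sprintf("candidate must have %d component(s)", length(side_sets)))
  universe <- unique(unlist(lapply(spec$sets, function(s) s$elements)))
  universe <- unique(c(universe, unlist(lapply(side_sets, function(s) s$elements))))
  unknown <- setdiff(candidate, universe)
  cs_assert(length(unknown) == 0L, "catsys_unknown_component",
            sprintf("unknown component(s): %s", paste(unknown, collapse = ", ")))
  label <- do.call(tuple_label, as.list(candidate))
  if (label %in% r$apex$elements) {
    return(list(member = TRUE, reason = "member", detail = label))
  }
  misplaced <- character(0)
  for (i in seq_along(candidate)) {
    if (!(candidate[i] %in% side_sets[[i]]$elements)) {
      misplaced <- c(misplaced, candidate[i])
    }
  }
  if (length(misplaced)) {
    list(member = FALSE, reason = "role_set",
         detail = sprintf("component(s) on the wrong side: %s",
                          paste(misplaced, collapse = ", ")))
  } else {
    list(member = FALSE, reason = "constraint",
         detail = "components are on their proper sides but the shared-attribute constraint fails")
  }
}

#' Quotient of a set by a classifier map
#'
#' Builds the equivalence classes of a classifier (its fibers) through the
#' kernel-pair coequalizer: the pullback of the classifier with itself gives
#' the kernel pair, and the coequalizer of its two projections is the
#' quotient. The quotient is isomorphic to the classifier's image, and the
#' isomorphism is returned.
#'
#' @param base an `fset`.
#' @param classifier an `fmap` total on `base`.
#' @param spec optionally, the originating [domain_spec()].
#' @return An object of class `quotient_structure` with fields `base`,
#'   `classifier`, `classes` (class label to members), `quotient` (`fset`
#'   of class labels), `class_map` (base -> quotient), and `image_iso`
#'   (quotient -> image of the classifier).
#' @export
quotient <- function(base, classifier, spec = NULL) {
  cs_assert(fset_equal(classifier$dom, base), "catsys_malformed_spec",
            "classifier must be total on base")
  kp <- pullback(classifier, classifier)
  coeq <- coequalizer(kp$legs$left, kp$legs$right)
  class_map <- coeq$legs$cod
  image <- fset(unique(unname(classifier$assignment)),
                name = paste0("im_", classifier$name))
  # each class maps to a single classifier value; that correspondence is the iso
  iso_asg <- vapply(coeq$apex$elements, function(cl)
    unname(classifier$assignment[[cl]]), character(1))
  image_iso <- fmap(coeq$apex, image,
                    structure(iso_asg, names = coeq$apex$elements),
                    name = "quot_iso")
  cs_assert(is_isomorphism(image_iso)$is_iso, "catsys_internal",
            "quotient is not isomorphic to the classifier image")
  structure(list(spec = spec, base = base, classifier = classifier,
                 classes = coeq$classes, quotient = coeq$apex,
                 class_map = class_map, image_iso = image_iso,
                 coequalizer = coeq),
            class = "quotient_structure")
}

#' @export
print.quotient_structure <- function(x, ...) {
  cat(sprintf("quotient of %s by %s: %d class(es)\n",
              format(x$base), x$classifier$name, length(x$classes)))
  for (cl in names(x$classes)) {
    cat(sprintf("  [%s] = {%s}\n", cl, paste(x$classes[[cl]], collapse = ", ")))
  }
  invisible(x)
}

#' Accessor architecture over a realized relation
#'
#' An architecture assigns, per relation instance, the accessor pair used to
#' read role fillers out of it: `canonical` (the mediating projections) or
#' `swapped` (the two non-constraint accessors exchanged). A uniform
#' canonical architecture factors through the single mediating construction;
#' any mixture is what [audit()] flags.
#'
#' @param r a `realized_relation`.
#' @param swapped character vector of apex instances assigned the swapped
#'   accessor pair (must all be apex elements).
#' @return An object of class `cat_architecture`.
#' @export
architecture <- function(r, swapped = character(0)) {
  bad <- setdiff(swapped, r$apex$elements)
  cs_assert(length(bad) == 0L, "catsys_malformed_spec",
            sprintf("instance(s) not in the apex: %s", paste(bad, collapse = ", ")))
  assignment <- structure(rep("canonical", fset_size(r$apex)),
                          names = r$apex$elements)
  assignment[swapped] <- "swapped"
  structure(list(relation = r, assignment = assignment),
            class = "cat_architecture")
}

swappable_roles <- function(r) {
  sides <- r$spec$roles[names(r$projections)]
  names(sides)[sides %in% c("left", "right")]
}

#' Audit an architecture for (quasi-)systematicity
#'
#' Passes exactly when every instance's accessors agree with the canonical
#' mediating projections — the element-wise restatement of "one and only one
#' way to realize the other capacities". A mixed architecture fails on every
#' swapped instance whose two role fillers differ: each counterexample
#' reports the role, the expected filler, and the filler the swapped
#' accessor actually produces (e.g. steer produced as progenitor of
#' (bull, steer)).
#'
#' @param arch a [architecture()].
#' @return A `catsys_report` with `ok` and `counterexamples`.
#' @export
audit <- function(arch) {
  r <- arch$relation
  roles <- swappable_roles(r)
  cs_assert(length(roles) == 2L, "catsys_wrong_style",
            "audit needs exactly two non-constraint roles")
  counterexamples <- list()
  for (x in r$apex$elements) {
    expected <- vapply(roles, function(ro)
      unname(r$projections[[ro]]$assignment[[x]]), character(1))
    produced <- if (arch$assignment[[x]] == "swapped") rev(expected) else expected
    for (i in seq_along(roles)) {
      if (produced[i] != expected[i]) {
        counterexamples[[length(counterexamples) + 1L]] <- list(
          instance = x, role = unname(roles[i]),
          expected = unname(expected[i]), produced = unname(produced[i]))
      }
    }
  }
  structure(list(ok = length(counterexamples) == 0L,
                 counterexamples = counterexamples,
                 failures = counterexamples),
            class = "catsys_report")
}

#' Block-matrix view of a shared-constraint relation
#'
#' Rows are the left set and columns the right set, each grouped by their
#' shared-attribute value; filled cells are exactly the apex instances, so
#' they form diagonal blocks, one per attribute value with members on both
#' sides.
#'
#' @param r a `realized_relation` of style `shared_constraint`.
#' @return An object of class `block_matrix`: logical cell matrix with
#'   grouped dimnames, the attribute of each row/column, the filled-cell
#'   count, and the block (attribute) labels.
#' @export
block_matrix <- function(r) {
  cs_assert(r$spec$style == "shared_constraint", "catsys_wrong_style",
            "block_matrix applies to shared_constraint relations")
  spec <- r$spec
  la <- spec$maps$left_attr; ra <- spec$maps$right_attr
  rows <- spec$sets$left$elements
  cols <- spec$sets$right$elements
  row_attr <- unname(la$assignment[rows])
  col_attr <- unname(ra$assignment[cols])
  ro <- order(row_attr, rows, method = "radix")
  co <- order(col_attr, cols, method = "radix")
  rows <- rows[ro]; row_attr <- row_attr[ro]
  cols <- cols[co]; col_attr <- col_attr[co]
  cells <- outer(rows, cols, function(a, b) tuple_label(a, b) %in% r$apex$elements)
  dimnames(cells) <- list(rows, cols)
  structure(list(cells = cells, row_attr = row_attr, col_attr = col_attr,
                 filled = sum(cells),
                 blocks = canon_sort(intersect(row_attr, col_attr))),
            class = "block_matrix")
}

#' @export
print.block_matrix <- function(x, ...) {
  rows <- rownames(x$cells); cols <- colnames(x$cells)
  wr <- max(nchar(c(rows, "")), 0)
  wc <- vapply(cols, nchar, integer(1))
  hdr <- paste0(formatC("", width = wr), " | ",
                paste(cols, collapse = " "), "")
  cat(hdr, "\n")
  cat(strrep("-", nchar(hdr)), "\n")
  prev_attr <- NULL
  for (i in seq_along(rows)) {
    if (!is.null(prev_attr) && x$row_attr[i] != prev_attr) {
      cat(strrep("-", nchar(hdr)), "\n")
    }
    prev_attr <- x$row_attr[i]
    marks <- vapply(seq_along(cols), function(j)
      formatC(if (x$cells[i, j]) "x" else ".", width = wc[j]), character(1))
    cat(formatC(rows[i], width = wr), " | ", paste(marks, collapse = " "), "\n",
        sep = "")
  }
  cat(sprintf("%d filled cell(s) in %d diagonal block(s)\n",
              x$filled, length(x$blocks)))
  invisible(x)
}
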