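# The ambient category: finite sets of opaque string labels and total maps
# between them. Everything downstream (diagrams, limits, adjunctions, the
# cognitive-domain layer) is built on these two value classes.

#' Finite set of labels
#'
#' The objects of the ambient category. Elements are opaque strings; tuple
#' elements are encoded as `"(x,y)"` labels (see [tuple_label()]). Elements
#' are stored de-duplicated in canonical (byte-lexicographic) order, which
#' makes all downstream enumeration deterministic. The name is display-only:
#' two `fset`s are equal when their element collections are equal.
#'
#' @param elements character vector of element labels.
#' @param name display name for the set.
#' @return An object of class `fset` with fields `name` and `elements`.
#' @examples
#' fset(c("mare", "stallion"), name = "Pr")
#' @export
fset <- function(elements = character(0), name = "") {
  elements <- as.character(elements)
  cs_assert(!anyNA(elements), "catsys_bad_set", "set elements must not be NA")
  structure(
    list(name = as.character(name)[1], elements = canon_sort(unique(elements))),
    class = "fset"
  )
}

#' @export
print.fset <- function(x, ...) {
  nm <- if (nzchar(x$name)) x$name else "<unnamed>"
  cat(sprintf("fset %s (%d elements)\n", nm, length(x$elements)))
  if (length(x$elements)) cat("  {", paste(x$elements, collapse = ", "), "}\n")
  invisible(x)
}

#' @export
format.fset <- function(x, ...) {
  paste0("{", paste(x$elements, collapse = ","), "}")
}

#' @rdname fset
#' @param x object to test or compare.
#' @export
is_fset <- function(x) inherits(x, "fset")

#' Extensional equality of finite sets
#'
#' @param x,y `fset` objects.
#' @return `TRUE` when the two element collections coincide (names ignored).
#' @export
fset_equal <- function(x, y) {
  identical(x$elements, y$elements)
}

fset_size <- function(x) length(x$elements)

#' Total map between finite sets
#'
#' The morphisms of the ambient category: a total function from `dom` to
#' `cod`, given element-wise. Totality and well-typedness are enforced at
#' construction. Equality of maps is extensional ([fmap_equal()]): same
#' domain elements, same codomain elements, same assignment.
#'
#' @param dom,cod `fset` domain and codomain.
#' @param assignment named character vector (or named list) mapping every
#'   domain element to a codomain element.
#' @param name display name for the map.
#' @return An object of class `fmap`.
#' @examples
#' S <- fset(c("equine", "bovine"), "S")
#' Pr <- fset(c("stallion", "mare", "bull", "cow"), "Pr")
#' fmap(Pr, S, c(stallion = "equine", mare = "equine",
#'               bull = "bovine", cow = "bovine"), name = "species")
#' @export
fmap <- function(dom, cod, assignment, name = "") {
  cs_assert(is_fset(dom) && is_fset(cod), "catsys_bad_map",
            "dom and cod must be fset objects")
  assignment <- unlist(assignment)
  if (length(assignment) == 0L) assignment <- structure(character(0), names = character(0))
  storage.mode(assignment) <- "character"
  missing <- setdiff(dom$elements, names(assignment))
  cs_assert(length(missing) == 0L, "catsys_partial_map",
            sprintf("map %s is not total: unassigned element(s) %s",
                    name, paste(missing, collapse = ", ")))
  extra <- setdiff(names(assignment), dom$elements)
  cs_assert(length(extra) == 0L, "catsys_bad_map",
            sprintf("map %s assigns element(s) outside its domain: %s",
                    name, paste(extra, collapse = ", ")))
  bad <- setdiff(unname(assignment), cod$elements)
  cs_assert(length(bad) == 0L, "catsys_bad_map",
            sprintf("map %s targets element(s) outside its codomain: %s",
                    name, paste(bad, collapse = ", ")))
  structure(
    list(name = as.character(name)[1], dom = dom, cod = cod,
         assignment = assignment[dom$elements]),
    class = "fmap"
  )
}

#' @rdname fmap
#' @param x object to test.
#' @export
is_fmap <- function(x) inherits(x, "fmap")

#' @export
print.fmap <- function(x, ...) {
  nm <- if (nzchar(x$name)) x$name else "<unnamed>"
  cat(sprintf("fmap %s: %s -> %s\n", nm,
              if (nzchar(x$dom$name)) x$dom$name else format(x$dom),
              if (nzchar(x$cod$name)) x$cod$name else format(x$cod)))
  if (length(x$assignment)) {
    cat(paste0("  ", names(x$assignment), " |-> ", unname(x$assignment),
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Apply a map to elements
#'
#' @param f an `fmap`.
#' @param x character vector of domain elements.
#' @return The image labels, in the order of `x`.
#' @export
apply_map <- function(f, x) {
  bad <- setdiff(x, f$dom$elements)
  cs_assert(length(bad) == 0L, "catsys_bad_element",
            sprintf("element(s) not in domain of %s: %s",
                    f$name, paste(bad, collapse = ", ")))
  unname(f$assignment[x])
}

#' Extensional equality of maps
#'
#' Two maps are equal when they have the same domain elements, the same
#' codomain elements, and the same assignment; names are ignored. This is
#' the notion of equality under which all diagram-commutativity and
#' uniqueness arguments are carried out.
#'
#' @param f,g `fmap` objects.
#' @export
fmap_equal <- function(f, g) {
  fset_equal(f$dom, g$dom) && fset_equal(f$cod, g$cod) &&
    identical(unname(f$assignment), unname(g$assignment))
}

#' Composition of maps
#'
#' `compose(g, f)` is the usual composite `g` after `f`: the map
#' `x |-> g(f(x))` with domain `dom(f)` and codomain `cod(g)`. Composition
#' requires `cod(f)` to equal `dom(g)` as an element collection.
#'
#' @param g,f `fmap` objects with `cod(f) = dom(g)`.
#' @param name optional display name; defaults to `"g.f"`.
#' @return The composite `fmap`.
#' @examples
#' A <- fset(c("a", "b")); B <- fset(c("x", "y")); C <- fset("z")
#' f <- fmap(A, B, c(a = "x", b = "y"))
#' g <- fmap(B, C, c(x = "z", y = "z"))
#' compose(g, f)
#' @export
compose <- function(g, f, name = NULL) {
  cs_assert(fset_equal(f$cod, g$dom), "catsys_composition_mismatch",
            sprintf("cannot compose: cod(%s) = %s differs from dom(%s) = %s",
                    f$name, format(f$cod), g$name, format(g$dom)))
  if (is.null(name)) {
    name <- paste0(if (nzchar(g$name)) g$name else "g", ".",
                   if (nzchar(f$name)) f$name else "f")
  }
  asg <- g$assignment[unname(f$assignment)]
  names(asg) <- names(f$assignment)
  fmap(f$dom, g$cod, asg, name = name)
}

#' Identity map on a set
#'
#' @param A an `fset`.
#' @return The `fmap` sending every element of `A` to itself.
#' @export
id_map <- function(A) {
  asg <- A$elements
  names(asg) <- A$elements
  fmap(A, A, asg, name = paste0("id_", if (nzchar(A$name)) A$name else "A"))
}

#' Test a map for being an isomorphism
#'
#' A map in the category of finite sets is an isomorphism exactly when its
#' assignment is a bijection. When it is, the inverse map is returned and
#' satisfies `compose(inverse, f) = id(dom)` and `compose(f, inverse) =
#' id(cod)`.
#'
#' @param f an `fmap`.
#' @return A list with `is_iso` (logical) and `inverse` (the inverse `fmap`,
#'   or `NULL` when `f` is not an isomorphism).
#' @export
is_isomorphism <- function(f) {
  targets <- unname(f$assignment)
  injective <- !anyDuplicated(targets)
  surjective <- setequal(targets, f$cod$elements)
  if (!(injective && surjective)) {
    return(list(is_iso = FALSE, inverse = NULL))
  }
  inv <- names(f$assignment)
  names(inv) <- targets
  list(is_iso = TRUE,
       inverse = fmap(f$cod, f$dom, inv,
                      name = paste0(if (nzchar(f$name)) f$name else "f", "^-1")))
}

#' Exhaustively enumerate all total maps between two sets
#'
#' Returns all `|B|^|A|` total maps from `A` to `B` in canonical
#' lexicographic order: the assignment is read as a word over the codomain
#' (domain elements in canonical order, first element most significant) and
#' words are in dictionary order. Conventions at the empty set: exactly one
#' map out of the empty set; no maps into the empty set from a nonempty one.
#'
#' @param A,B `fset` objects.
#' @param cap refuse to enumerate more than this many maps (default `1e6`);
#'   exceeding it raises a `catsys_cap_exceeded` error reporting the count
#'   that would have been required.
#' @return A list of `fmap` objects.
#' @export
enumerate_maps <- function(A, B, cap = 1e6) {
  nA <- fset_size(A)
  nB <- fset_size(B)
  total <- if (nA == 0L) 1 else nB^nA
  cs_assert(total <= cap, "catsys_cap_exceeded",
            sprintf("enumeration of %s maps %s -> %s exceeds cap %s",
                    format(total, scientific = FALSE), A$name, B$name,
                    format(cap, scientific = FALSE)))
  if (nA == 0L) {
    return(list(fmap(A, B, character(0), name = "empty")))
  }
  if (nB == 0L) return(list())
  # expand.grid varies the first factor fastest; to get dictionary order with
  # the first domain element most significant, feed domain elements reversed.
  grid <- do.call(expand.grid, c(rep(list(B$elements), nA),
                                 list(stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_len(nA)), drop = FALSE]
  ord <- do.call(order, c(as.list(grid), list(method = "radix")))
  grid <- grid[ord, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    asg <- as.character(grid[i, ])
    names(asg) <- A$elements
    fmap(A, B, asg, name = sprintf("m%d", i))
  })
}
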