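# The diagonal -| product adjunction, verified rather than assumed: functors
# as extensional object/map actions, the unit a |-> (a,a) and counit
# (p1, p2), naturality and triangle identities, the universal-arrow
# factorization in both the unit and counit presentations, and the hom-set
# bijection. Deliberately non-adjoint candidates (swapped or mixed accessor
# assignments, degenerate units) are constructible so that the verifier can
# demonstrate their failure.

#' Ordered pair of finite sets / maps (the pair category)
#'
#' Objects and morphisms of the product category in which the product
#' functor lands: a `pair_object` is an ordered pair of `fset`s, a
#' `pair_map` an ordered pair of `fmap`s acting componentwise.
#'
#' @param left,right `fset`s (for `pair_object`) or `fmap`s (for `pair_map`).
#' @return A `pair_object` / `pair_map`.
#' @export
pair_object <- function(left, right) {
  cs_assert(is_fset(left) && is_fset(right), "catsys_bad_pair",
            "pair_object needs two fsets")
  structure(list(left = left, right = right), class = "pair_object")
}

#' @rdname pair_object
#' @export
pair_map <- function(left, right) {
  cs_assert(is_fmap(left) && is_fmap(right), "catsys_bad_pair",
            "pair_map needs two fmaps")
  structure(list(left = left, right = right), class = "pair_map")
}

pair_compose <- function(g, f) {
  pair_map(compose(g$left, f$left), compose(g$right, f$right))
}

pair_id <- function(p) pair_map(id_map(p$left), id_map(p$right))

pair_map_equal <- function(f, g) {
  fmap_equal(f$left, g$left) && fmap_equal(f$right, g$right)
}

#' Functor as an extensional object/map action
#'
#' Functors are represented by their actions evaluated on demand (the
#' ambient category is too large for total tables); the functor laws are
#' checked on probe objects and maps by [check_functor_laws()].
#'
#' @param name display name.
#' @param on_object function from objects to objects.
#' @param on_map function from maps to maps.
#' @return An object of class `functor_spec`.
#' @export
functor_spec <- function(name, on_object, on_map) {
  structure(list(name = name, on_object = on_object, on_map = on_map),
            class = "functor_spec")
}

#' The pair diagonal functor
#'
#' Sends a set `A` to the pair `(A, A)` and a map `f` to `(f, f)`; the left
#' adjoint of the product functor.
#'
#' @return A [functor_spec()].
#' @export
diagonal_functor <- function() {
  functor_spec("diagonal",
               on_object = function(A) pair_object(A, A),
               on_map = function(f) pair_map(f, f))
}

#' The product functor and its non-adjoint look-alikes
#'
#' `product_functor()` sends a pair `(A, B)` to the canonical product apex
#' `A x B` and a pair map `(f, g)` to `f x g : (a,b) |-> (f(a), g(b))`. Its
#' `accessors` field returns, per pair object, the accessor pair the
#' architecture uses to read components back out — the counit components.
#' `swapped_product_functor()` keeps the object and map actions but exchanges
#' the two accessors everywhere; `mixed_product_functor(select)` swaps them
#' only on pair objects for which `select(p)` is `TRUE`. The swapped
#' construction is still a product in isolation, but paired with the
#' unchanged diagonal unit it no longer forms an adjunction — which is
#' exactly what [verify_adjunction()] detects.
#'
#' @param select for `mixed_product_functor`, predicate on a `pair_object`.
#' @return A [functor_spec()] with an extra `accessors` field:
#'   `function(p)` returning a list of two `fmap`s out of the product object.
#' @export
product_functor <- function() {
  make_product_functor(function(p) FALSE, "product")
}

#' @rdname product_functor
#' @export
swapped_product_functor <- function() {
  make_product_functor(function(p) TRUE, "product_swapped")
}

#' @rdname product_functor
#' @export
mixed_product_functor <- function(select) {
  make_product_functor(select, "product_mixed")
}

make_product_functor <- function(swap_on, name) {
  on_object <- function(p) product(p$left, p$right)$apex
  on_map <- function(pm) {
    dom_cone <- product(pm$left$dom, pm$right$dom)
    cod_apex <- product(pm$left$cod, pm$right$cod)$apex
    a <- unname(dom_cone$legs$left$assignment)
    b <- unname(dom_cone$legs$right$assignment)
    img <- tuple_label(unname(pm$left$assignment[a]),
                       unname(pm$right$assignment[b]))
    fmap(dom_cone$apex, cod_apex,
         structure(img, names = dom_cone$apex$elements),
         name = paste0(pm$left$name, "x", pm$right$name))
  }
  f <- functor_spec(name, on_object, on_map)
  f$accessors <- function(p) {
    cone <- product(p$left, p$right)
    acc <- list(cone$legs$left, cone$legs$right)
    if (isTRUE(swap_on(p))) acc <- rev(acc)
    acc
  }
  f
}

#' Unit and counit of the diagonal-product adjunction
#'
#' The unit component at `A` is the pairing map `a |-> (a,a) : A -> A x A`;
#' the counit component at `(A, B)` is the projection pair
#' `(p1, p2) : (A x B, A x B) -> (A, B)`. Neither formula is arbitrary: both
#' are forced by the universal property, which [verify_adjunction()]
#' confirms independently.
#'
#' @param A an `fset`.
#' @param p a [pair_object()].
#' @return `unit_component()`: an `fmap` `A -> A x A`;
#'   `counit_component()`: a [pair_map()].
#' @export
unit_component <- function(A) {
  apex <- product(A, A)$apex
  fmap(A, apex, structure(tuple_label(A$elements, A$elements),
                          names = A$elements),
       name = paste0("eta_", A$name))
}

#' @rdname unit_component
#' @export
counit_component <- function(p) {
  cone <- product(p$left, p$right)
  pair_map(cone$legs$left, cone$legs$right)
}

#' Check functor laws on probe objects and maps
#'
#' Verifies identity preservation on each probe object and composition
#' preservation on each composable pair drawn from `maps`. Works for
#' functors between the base and pair categories in either direction; values
#' are compared extensionally.
#'
#' @param F a [functor_spec()].
#' @param objects list of probe objects (each `fset` or `pair_object`).
#' @param maps list of probe maps (each `fmap` or `pair_map`).
#' @return A `catsys_report`.
#' @export
check_functor_laws <- function(F, objects, maps) {
  failures <- list()
  gen_id <- function(x) if (is_fset(x)) id_map(x) else pair_id(x)
  gen_compose <- function(g, f) {
    if (is_fmap(f)) compose(g, f) else pair_compose(g, f)
  }
  gen_equal <- function(a, b) {
    if (is_fmap(a) && is_fmap(b)) fmap_equal(a, b)
    else if (inherits(a, "pair_map") && inherits(b, "pair_map")) pair_map_equal(a, b)
    else FALSE
  }
  gen_dom <- function(f) if (is_fmap(f)) f$dom else pair_object(f$left$dom, f$right$dom)
  gen_cod <- function(f) if (is_fmap(f)) f$cod else pair_object(f$left$cod, f$right$cod)
  obj_equal <- function(a, b) {
    if (is_fset(a) && is_fset(b)) fset_equal(a, b)
    else if (inherits(a, "pair_object") && inherits(b, "pair_object"))
      fset_equal(a$left, b$left) && fset_equal(a$right, b$right)
    else FALSE
  }
  for (A in objects) {
    lhs <- F$on_map(gen_id(A))
    rhs <- gen_id(F$on_object(A))
    if (!gen_equal(lhs, rhs)) {
      failures[[length(failures) + 1L]] <- list(law = "identity", object = A)
    }
  }
  for (f in maps) for (g in maps) {
    if (!obj_equal(gen_cod(f), gen_dom(g))) next
    lhs <- F$on_map(gen_compose(g, f))
    rhs <- gen_compose(F$on_map(g), F$on_map(f))
    if (!gen_equal(lhs, rhs)) {
      failures[[length(failures) + 1L]] <- list(law = "composition")
    }
  }
  structure(list(ok = length(failures) == 0L, failures = failures),
            class = "catsys_report")
}

#' Check naturality of a transformation on probe maps
#'
#' For every probe map `f : A -> B`, the square
#' `target(f) . component(A) = component(B) . source(f)` must commute.
#'
#' @param source,target [functor_spec()]s with a common domain category.
#' @param component function from a domain object to the component morphism.
#' @param maps probe maps in the domain category.
#' @return A `catsys_report`.
#' @export
check_naturality <- function(source, target, component, maps) {
  failures <- list()
  gen_compose <- function(g, f) if (is_fmap(f)) compose(g, f) else pair_compose(g, f)
  gen_equal <- function(a, b) {
    if (is_fmap(a)) fmap_equal(a, b) else pair_map_equal(a, b)
  }
  gen_dom <- function(f) if (is_fmap(f)) f$dom else pair_object(f$left$dom, f$right$dom)
  gen_cod <- function(f) if (is_fmap(f)) f$cod else pair_object(f$left$cod, f$right$cod)
  for (f in maps) {
    lhs <- gen_compose(target$on_map(f), component(gen_dom(f)))
    rhs <- gen_compose(component(gen_cod(f)), source$on_map(f))
    if (!gen_equal(lhs, rhs)) {
      failures[[length(failures) + 1L]] <- list(square = "naturality")
    }
  }
  structure(list(ok = length(failures) == 0L, failures = failures),
            class = "catsys_report")
}

#' Verify a candidate diagonal-product adjunction exhaustively
#'
#' Runs, over all probe objects (and all ordered pairs of them as pair
#' objects), every finite obligation of the adjunction:
#' \itemize{
#'   \item functor laws for both functors,
#'   \item naturality of the unit,
#'   \item counit-side factorization: for every pair of maps
#'     `f1 : A -> B1`, `f2 : A -> B2` there is exactly one
#'     `h : A -> G(B1,B2)` with `acc1 . h = f1` and `acc2 . h = f2`, where
#'     `(acc1, acc2)` are the functor's accessors at `(B1, B2)`,
#'   \item unit-side factorization: for every `u : A -> G(B)` there is
#'     exactly one pair map `fhat : (A,A) -> B` with
#'     `G(fhat) . unit(A) = u`,
#'   \item both triangle identities.
#' }
#' All searches are exhaustive over [enumerate_maps()] under `cap`.
#'
#' @param left the left-adjoint candidate (default [diagonal_functor()]).
#' @param right the right-adjoint candidate with an `accessors` field
#'   (default [product_functor()]).
#' @param unit function from an `fset` `A` to the unit component at `A`
#'   (default [unit_component()]).
#' @param probes list of probe `fset`s; defaults to [default_probes()].
#' @param cap enumeration cap.
#' @return A `catsys_report` with `ok`, `checks` (named pass counts) and
#'   `failures` (each naming the obligation and a counterexample).
#' @export
verify_adjunction <- function(left = diagonal_functor(),
                              right = product_functor(),
                              unit = unit_component,
                              probes = default_probes(),
                              cap = 1e6) {
  failures <- list()
  checks <- c(functor_laws = 0L, unit_naturality = 0L,
              counit_factorization = 0L, unit_factorization = 0L,
              triangle = 0L)
  fail <- function(kind, detail) {
    failures[[length(failures) + 1L]] <<- list(obligation = kind, detail = detail)
  }
  safe_equal <- function(a, b) {
    fset_equal(a$dom, b$dom) && fset_equal(a$cod, b$cod) &&
      identical(unname(a$assignment), unname(b$assignment))
  }

  base_maps <- list()
  for (A in probes) for (B in probes) {
    base_maps <- c(base_maps, enumerate_maps(A, B, cap = cap))
  }
  pair_objects <- list()
  for (A in probes) for (B in probes) {
    pair_objects[[length(pair_objects) + 1L]] <- pair_object(A, B)
  }
  pair_maps <- lapply(base_maps, function(f) pair_map(f, f))

  rep_laws_left <- check_functor_laws(left, probes, base_maps)
  rep_laws_right <- check_functor_laws(right, pair_objects, pair_maps)
  checks["functor_laws"] <- 2L
  if (!rep_laws_left$ok) fail("functor_laws", "left functor violates a law")
  if (!rep_laws_right$ok) fail("functor_laws", "right functor violates a law")

  # unit naturality: G(F(f)) . eta_A = eta_B . f
  GF <- functor_spec("GF",
                     on_object = function(A) right$on_object(left$on_object(A)),
                     on_map = function(f) right$on_map(left$on_map(f)))
  rep_nat <- check_naturality(functor_spec("Id", identity, identity),
                              GF, unit, base_maps)
  checks["unit_naturality"] <- length(base_maps)
  if (!rep_nat$ok) fail("unit_naturality", "a naturality square fails")

  for (A in probes) {
    eta_A <- unit(A)
    for (p in pair_objects) {
      G_obj <- right$on_object(p)
      acc <- right$accessors(p)
      hs <- enumerate_maps(A, G_obj, cap = cap)
      f1s <- enumerate_maps(A, p$left, cap = cap)
      f2s <- enumerate_maps(A, p$right, cap = cap)
      for (f1 in f1s) for (f2 in f2s) {
        n_ok <- sum(vapply(hs, function(h) {
          safe_equal(compose(acc[[1]], h), f1) &&
            safe_equal(compose(acc[[2]], h), f2)
        }, logical(1)))
        checks["counit_factorization"] <- checks["counit_factorization"] + 1L
        if (n_ok != 1L) {
          fail("counit_factorization",
               sprintf("A=%s B=(%s,%s) f1=[%s] f2=[%s]: %d mediating map(s)",
                       format(A), format(p$left), format(p$right),
                       paste(f1$assignment, collapse = ","),
                       paste(f2$assignment, collapse = ","), n_ok))
        }
      }
      # unit-side: every u: A -> G(B) transposes to exactly one fhat: FA -> B
      us <- hs
      fhat1s <- f1s
      fhat2s <- f2s
      for (u in us) {
        n_ok <- 0L
        for (fh1 in fhat1s) for (fh2 in fhat2s) {
          Gfh <- right$on_map(pair_map(fh1, fh2))
          cand <- tryCatch(compose(Gfh, eta_A), catsys_error = function(e) NULL)
          if (!is.null(cand) && safe_equal(cand, u)) n_ok <- n_ok + 1L
        }
        checks["unit_factorization"] <- checks["unit_factorization"] + 1L
        if (n_ok != 1L) {
          fail("unit_factorization",
               sprintf("A=%s B=(%s,%s) u=[%s]: %d transpose(s)",
                       format(A), format(p$left), format(p$right),
                       paste(u$assignment, collapse = ","), n_ok))
        }
      }
    }
    # triangle 1: acc_i(F A) . eta_A = id_A for both accessors
    accFA <- right$accessors(left$on_object(A))
    for (i in 1:2) {
      checks["triangle"] <- checks["triangle"] + 1L
      lhs <- tryCatch(compose(accFA[[i]], eta_A), catsys_error = function(e) NULL)
      if (is.null(lhs) || !safe_equal(lhs, id_map(A))) {
        fail("triangle", sprintf("triangle 1 fails at A=%s (component %d)",
                                 format(A), i))
      }
    }
  }
  # triangle 2: G(counit_B) . eta_{G B} = id_{G B} for every pair object
  for (p in pair_objects) {
    G_obj <- right$on_object(p)
    acc <- right$accessors(p)
    checks["triangle"] <- checks["triangle"] + 1L
    lhs <- tryCatch(compose(right$on_map(pair_map(acc[[1]], acc[[2]])),
                            unit(G_obj)),
                    catsys_error = function(e) NULL)
    if (is.null(lhs) || !safe_equal(lhs, id_map(G_obj))) {
      fail("triangle", sprintf("triangle 2 fails at B=(%s,%s)",
                               format(p$left), format(p$right)))
    }
  }
  structure(list(ok = length(failures) == 0L, checks = checks,
                 failures = failures),
            class = "catsys_report")
}

#' Hom-set bijection of the diagonal-product adjunction
#'
#' Enumerates the hom-set `Hom((A,A), (B1,B2))` in the pair category and
#' `Hom(A, B1 x B2)` in the base category, and checks that
#' `h |-> (p1 . h, p2 . h)` is a one-to-one correspondence between them.
#'
#' @param A an `fset`.
#' @param p a [pair_object()] `(B1, B2)`.
#' @param cap enumeration cap for both hom-sets.
#' @return A `catsys_report` with fields `hom_pair` and `hom_base` (the two
#'   cardinalities) and `ok`.
#' @export
hom_set_bijection <- function(A, p, cap = 1e6) {
  cone <- product(p$left, p$right)
  hom_base <- enumerate_maps(A, cone$apex, cap = cap)
  n_pair <- (if (fset_size(A) == 0L) 1
             else fset_size(p$left)^fset_size(A) * fset_size(p$right)^fset_size(A))
  cs_assert(n_pair <= cap, "catsys_cap_exceeded", "pair hom-set exceeds cap")
  seen <- character(0)
  ok <- TRUE
  for (h in hom_base) {
    f1 <- compose(cone$legs$left, h)
    f2 <- compose(cone$legs$right, h)
    key <- paste(paste(f1$assignment, collapse = ","),
                 paste(f2$assignment, collapse = ","), sep = "|")
    if (key %in% seen) ok <- FALSE  # not injective
    seen <- c(seen, key)
  }
  if (length(hom_base) != n_pair) ok <- FALSE  # not surjective onto the pair hom-set
  structure(list(ok = ok, hom_pair = n_pair, hom_base = length(hom_base),
                 failures = if (ok) list() else list(list(reason = "not a bijection"))),
            class = "catsys_report")
}
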