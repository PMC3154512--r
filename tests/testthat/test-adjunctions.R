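# Functors, unit/counit, adjunction verification, hom-set bijection.

test_that("diagonal and product functors satisfy the functor laws on random maps", {
  A <- letters_set(3, "A"); B <- fset(c("x", "y"), "B"); C <- fset(c("u", "v", "w"), "C")
  Dg <- diagonal_functor(); Pf <- product_functor()
  set.seed(111)
  maps <- list()
  for (k in 1:200) maps[[k]] <- random_fmap(A, B)
  # identity preservation
  dA <- Dg$on_map(id_map(A))
  expect_true(fmap_equal(dA$left, id_map(A)) && fmap_equal(dA$right, id_map(A)))
  expect_true(fmap_equal(Pf$on_map(pair_map(id_map(A), id_map(B))),
                         id_map(product(A, B)$apex)))
  # composition preservation, incl. the interchange law (g.f) x (k.h) = (gxk).(fxh)
  for (k in 1:50) {
    f <- random_fmap(A, B); g <- random_fmap(B, C)
    h <- random_fmap(A, B); kk <- random_fmap(B, C)
    d1 <- Dg$on_map(compose(g, f))
    expect_true(fmap_equal(d1$left, compose(g, f)))
    lhs <- Pf$on_map(pair_map(compose(g, f), compose(kk, h)))
    rhs <- compose(Pf$on_map(pair_map(g, kk)), Pf$on_map(pair_map(f, h)))
    expect_true(fmap_equal(lhs, rhs))
  }
  # forced small case
  fx <- fmap(fset("a"), fset("x"), c(a = "x"))
  gy <- fmap(fset("b"), fset("y"), c(b = "y"))
  expect_identical(apply_map(Pf$on_map(pair_map(fx, gy)), "(a,b)"), "(x,y)")
  laws <- check_functor_laws(Pf,
                             list(pair_object(A, B), pair_object(B, C)),
                             list(pair_map(random_fmap(A, B), random_fmap(B, C))))
  expect_true(laws$ok)
})

test_that("unit and counit components are natural and recover coordinates", {
  A <- fset(c("a"), "A")
  expect_identical(apply_map(unit_component(A), "a"), "(a,a)")
  B <- fset(c("x", "y"), "B"); C <- letters_set(3, "C")
  Pf <- product_functor()
  set.seed(222)
  for (k in 1:30) {
    f <- random_fmap(C, B)
    lhs <- compose(Pf$on_map(pair_map(f, f)), unit_component(C))
    rhs <- compose(unit_component(B), f)
    expect_true(fmap_equal(lhs, rhs))
  }
  agents <- fset(c("John", "Mary", "Sue", "Tom"), "agents")
  eps <- counit_component(pair_object(agents, agents))
  expect_identical(apply_map(eps$left, "(Sue,Tom)"), "Sue")
  expect_identical(apply_map(eps$right, "(Sue,Tom)"), "Tom")
  nat <- check_naturality(functor_spec("Id", identity, identity),
                          functor_spec("GF",
                                       function(A) product(A, A)$apex,
                                       function(f) Pf$on_map(pair_map(f, f))),
                          unit_component,
                          lapply(1:20, function(k) random_fmap(C, B)))
  expect_true(nat$ok)
})

test_that("the diagonal-product adjunction verifies on all probes", {
  rep <- verify_adjunction()
  expect_true(rep$ok)
  expect_true(rep$checks["counit_factorization"] > 0)
  expect_true(rep$checks["unit_factorization"] > 0)
  expect_true(rep$checks["triangle"] > 0)
})

test_that("swapped accessors with an unchanged unit break the adjunction with a counterexample", {
  rep <- verify_adjunction(right = swapped_product_functor())
  expect_false(rep$ok)
  kinds <- vapply(rep$failures, function(f) f$obligation, character(1))
  expect_true("counit_factorization" %in% kinds)
  detail <- rep$failures[[which(kinds == "counit_factorization")[1]]]$detail
  expect_match(detail, "0 mediating")
})

test_that("a mixed accessor assignment fails while the uniform one passes", {
  # swap accessors only on pair objects whose components differ
  mixed <- mixed_product_functor(function(p) !fset_equal(p$left, p$right))
  expect_false(verify_adjunction(right = mixed)$ok)
  expect_true(verify_adjunction(right = mixed_product_functor(function(p) FALSE))$ok)
})

test_that("a constant unit fails existence of the universal factorization", {
  const_unit <- function(A) {
    apex <- product(A, A)$apex
    if (fset_size(A) == 0L) return(unit_component(A))
    fmap(A, apex,
         structure(rep(tuple_label(A$elements[1], A$elements[1]),
                       fset_size(A)), names = A$elements))
  }
  rep <- verify_adjunction(unit = const_unit)
  expect_false(rep$ok)
  kinds <- vapply(rep$failures, function(f) f$obligation, character(1))
  expect_true("unit_factorization" %in% kinds)
})

test_that("the hom-set bijection holds with the predicted cardinalities", {
  A1 <- fset("a", "A1")
  B <- pair_object(fset(c("x", "y"), "B1"), fset(c("u", "v"), "B2"))
  rep <- hom_set_bijection(A1, B)
  expect_true(rep$ok)
  expect_identical(rep$hom_pair, 4)
  expect_identical(rep$hom_base, 4L)
  empty <- hom_set_bijection(fset(character(0)), B)
  expect_true(empty$ok)
  expect_identical(empty$hom_pair, 1)
  expect_identical(empty$hom_base, 1L)
  for (X in default_probes()) {
    for (p in list(B, pair_object(fset("z"), fset(c("x", "y"))))) {
      r <- hom_set_bijection(X, p)
      expect_true(r$ok)
      expect_identical(as.numeric(r$hom_base), as.numeric(r$hom_pair))
    }
  }
})
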