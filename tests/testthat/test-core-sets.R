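# The ambient category: sets, maps, composition, isomorphisms, enumeration.

test_that("composition follows element-wise double lookup and rejects mismatches", {
  A <- letters_set(4, "A")
  B <- fset(c("x", "y", "z"), "B")
  C <- fset(c("p", "q"), "C")
  set.seed(101)
  for (k in 1:20) {
    f <- random_fmap(A, B)
    g <- random_fmap(B, C)
    gf <- compose(g, f)
    for (a in A$elements) {
      expect_identical(apply_map(gf, a), apply_map(g, apply_map(f, a)))
    }
    expect_true(fset_equal(gf$dom, A))
    expect_true(fset_equal(gf$cod, C))
  }
  expect_error(compose(random_fmap(A, B), random_fmap(A, C)),
               class = "catsys_composition_mismatch")
})

test_that("a forced single path composes to the only possible map", {
  one <- fset("1", "1")
  X <- fset("x", "X")
  PQ <- fset(c("p", "q"), "PQ")
  f <- fmap(one, X, c(`1` = "x"))
  g <- fmap(X, PQ, c(x = "q"))
  expect_identical(apply_map(compose(g, f), "1"), "q")
})

test_that("identity and associativity laws hold on random maps", {
  A <- letters_set(3, "A"); B <- letters_set(5, "B"); C <- fset(c("u", "v"), "C")
  D <- fset(c("m", "n", "o"), "D")
  expect_length(id_map(fset(character(0)))$assignment, 0L)
  expect_identical(apply_map(id_map(fset("a")), "a"), "a")
  set.seed(202)
  for (k in 1:25) {
    f <- random_fmap(A, B); g <- random_fmap(B, C); h <- random_fmap(C, D)
    expect_true(fmap_equal(compose(id_map(B), f), f))
    expect_true(fmap_equal(compose(f, id_map(A)), f))
    expect_true(fmap_equal(compose(h, compose(g, f)),
                           compose(compose(h, g), f)))
  }
})

test_that("is_isomorphism agrees with the injective-and-surjective oracle", {
  A <- letters_set(5, "A")
  expect_true(is_isomorphism(id_map(A))$is_iso)
  expect_true(fmap_equal(is_isomorphism(id_map(A))$inverse, id_map(A)))
  const <- fmap(fset(c("a", "b")), fset("x"), c(a = "x", b = "x"))
  expect_false(is_isomorphism(const)$is_iso)
  set.seed(303)
  perm <- fmap(A, A, structure(sample(A$elements), names = A$elements))
  res <- is_isomorphism(perm)
  expect_true(res$is_iso)
  expect_true(fmap_equal(compose(res$inverse, perm), id_map(A)))
  expect_true(fmap_equal(compose(perm, res$inverse), id_map(A)))
  B <- letters_set(4, "B")
  for (k in 1:40) {
    f <- random_fmap(B, B)
    t <- unname(f$assignment)
    oracle <- !anyDuplicated(t) && setequal(t, B$elements)
    expect_identical(is_isomorphism(f)$is_iso, oracle)
  }
})

test_that("map enumeration is complete, canonical and capped", {
  A <- fset("a"); B <- fset(c("x", "y"))
  expect_length(enumerate_maps(A, B), 2L)
  # empty-domain convention: exactly one empty map
  expect_length(enumerate_maps(fset(character(0)), fset("x")), 1L)
  # no maps into the empty set from a nonempty one
  expect_length(enumerate_maps(A, fset(character(0))), 0L)
  maps <- enumerate_maps(letters_set(2), fset(c("x", "y", "z")))
  expect_length(maps, 9L)
  keys <- vapply(maps, function(m) paste(m$assignment, collapse = ""), character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(keys, sort(keys, method = "radix"))  # canonical order
  err <- tryCatch(enumerate_maps(letters_set(10), letters_set(10), cap = 100),
                  catsys_cap_exceeded = function(e) conditionMessage(e))
  expect_match(err, "10000000000")  # reports the required count
})
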