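# Universal constructions: products, pullbacks, (co)equalizers, pushouts,
# generic limits/colimits, mediating morphisms, universal-property checks.

test_that("product apex is the full Cartesian product with coordinate projections", {
  expect_identical(product(fset("a"), fset("b"))$apex$elements, "(a,b)")
  agents <- fset(c("John", "Mary", "Sue", "Tom"), "agents")
  pr <- product(agents, agents)
  expect_true("(Sue,Tom)" %in% pr$apex$elements)
  expect_identical(apply_map(pr$legs$left, "(Sue,Tom)"), "Sue")
  A <- letters_set(2); B <- fset(c("x", "y", "z"))
  # nested-loop oracle
  oracle <- character(0)
  for (a in A$elements) for (b in B$elements) oracle <- c(oracle, tuple_label(a, b))
  expect_setequal(product(A, B)$apex$elements, oracle)
  expect_length(product(A, B)$apex$elements, 6L)
})

test_that("pullback apex matches the comprehension oracle on seeded random instances", {
  A <- letters_set(5, "A"); B <- fset(paste0("b", 1:5), "B")
  C <- fset(c("u", "v", "w"), "C")
  set.seed(404)
  for (k in 1:200) {
    f <- random_fmap(A, C); g <- random_fmap(B, C)
    pb <- pullback(f, g)
    expect_identical(pb$apex$elements, comprehension_pullback(f, g))
    expect_true(check_commutative(pb$diagram)$ok)
  }
  expect_error(pullback(random_fmap(A, C), random_fmap(A, B)),
               class = "catsys_codomain_mismatch")
})

test_that("a singleton constraint gives no constraint: pullback collapses to the product", {
  A <- letters_set(3, "A"); B <- fset(c("x", "y"), "B")
  one <- fset("*", "1")
  pb <- pullback(fn_fmap(A, one, function(x) "*"),
                 fn_fmap(B, one, function(x) "*"))
  expect_identical(pb$apex$elements, product(A, B)$apex$elements)
})

test_that("equalizer carves out the agreement subset and matches its pullback presentation", {
  A <- fset(c("a", "b", "c"), "A")
  f <- id_map(A)
  g <- fn_fmap(A, A, function(x) "c")
  expect_identical(equalizer(f, g)$apex$elements, "c")
  expect_identical(equalizer(f, f)$apex$elements, A$elements)
  # oracle: the equalizer is the pullback of the pairing <f,g> along the diagonal
  B <- fset(c("x", "y"), "B")
  set.seed(505)
  f2 <- random_fmap(A, B); g2 <- random_fmap(A, B)
  pairing <- fn_fmap(A, product(B, B)$apex,
                     function(a) tuple_label(f2$assignment[[a]], g2$assignment[[a]]))
  diag_b <- fn_fmap(B, product(B, B)$apex, function(b) tuple_label(b, b))
  via_pb <- vapply(tuple_split(pullback(pairing, diag_b)$apex$elements),
                   `[[`, character(1), 1L)
  expect_identical(equalizer(f2, g2)$apex$elements, sort(via_pb, method = "radix"))
})

test_that("coequalizer classes are the generated equivalence, labelled by least member", {
  A <- fset(c("1", "2"), "A"); B <- fset(c("x", "y", "z"), "B")
  f <- fmap(A, B, c(`1` = "x", `2` = "y"))
  g <- fmap(A, B, c(`1` = "y", `2` = "z"))
  cq <- coequalizer(f, g)          # union-find oracle: one class {x,y,z}
  expect_identical(cq$apex$elements, "x")
  expect_setequal(cq$classes[["x"]], c("x", "y", "z"))
  same <- coequalizer(f, f)        # f = g: all classes singletons
  expect_identical(same$apex$elements, B$elements)
  # classes always partition the codomain
  set.seed(606)
  for (k in 1:25) {
    h1 <- random_fmap(A, B); h2 <- random_fmap(A, B)
    cl <- coequalizer(h1, h2)$classes
    expect_identical(sort(unlist(cl, use.names = FALSE), method = "radix"),
                     B$elements)
  }
})

test_that("kernel-pair coequalizer of the absolute map merges sign pairs", {
  w <- fset(as.character(-3:3), "window")
  mags <- fset(as.character(0:3), "mags")
  absmap <- fn_fmap(w, mags, function(x) as.character(abs(as.integer(x))))
  kp <- pullback(absmap, absmap)
  cq <- coequalizer(kp$legs$left, kp$legs$right)
  expect_length(cq$classes, 4L)
  merged <- cq$classes[[which(vapply(cq$classes, function(m) "3" %in% m, logical(1)))]]
  expect_setequal(merged, c("3", "-3"))
})

test_that("pushout generalizes coequalizer: the induced partition on the codomain agrees", {
  A <- fset(c("a", "b"), "A"); B <- fset(c("x", "y", "z"), "B")
  set.seed(707)
  f <- random_fmap(A, B); g <- random_fmap(A, B)
  # coequalizer as a pushout: push [f,g] : A+A -> B along the fold A+A -> A
  AA <- coproduct(A, A)
  bracket <- fn_fmap(AA$apex, B, function(t) {
    el <- sub("^(left|right):", "", t)
    if (startsWith(t, "left:")) f$assignment[[el]] else g$assignment[[el]]
  })
  fold <- fn_fmap(AA$apex, A, function(t) sub("^(left|right):", "", t))
  po <- pushout(bracket, fold)
  part_po <- split(B$elements, unname(po$legs$left$assignment[B$elements]))
  part_cq <- coequalizer(f, g)$classes
  canon <- function(p) sort(unname(vapply(p, function(m)
    paste(sort(m, method = "radix"), collapse = ","), character(1))),
    method = "radix")
  expect_identical(canon(part_po), canon(part_cq))
})

test_that("limits specialize correctly: terminal, product, pullback", {
  empty <- cat_diagram(cat_shape(character(0)), list(), list())
  expect_identical(limit(empty)$apex$elements, "()")
  A <- letters_set(2, "A"); B <- fset(c("x", "y", "z"), "B")
  disc <- cat_diagram(discrete_shape(c("left", "right")),
                      list(left = A, right = B))
  expect_length(limit(disc)$apex$elements, 6L)
  expect_true(universal_iso(limit(disc), product(A, B))$ok)
  p <- realize(fixture("parent"))
  lim <- limit(p$diagram)
  expect_length(lim$apex$elements, length(p$apex$elements))
  expect_true(universal_iso(lim, p$cone)$ok)
})

test_that("colimit of a parallel pair matches the coequalizer partition", {
  A <- fset(c("a", "b"), "A"); B <- fset(c("x", "y", "z"), "B")
  set.seed(808)
  f <- random_fmap(A, B); g <- random_fmap(A, B)
  d <- cat_diagram(cat_shape(c("dom", "cod"),
                             data.frame(name = c("f", "g"),
                                        from = c("dom", "dom"),
                                        to = c("cod", "cod"))),
                   list(dom = A, cod = B), list(f = f, g = g))
  co <- colimit(d)
  part_co <- split(B$elements, unname(co$legs$cod$assignment[B$elements]))
  part_cq <- coequalizer(f, g)$classes
  canon <- function(p) sort(unname(vapply(p, function(m)
    paste(sort(m, method = "radix"), collapse = ","), character(1))),
    method = "radix")
  expect_identical(canon(part_co), canon(part_cq))
  expect_length(co$apex$elements, length(part_cq))
})

test_that("the mediating morphism is the unique survivor of exhaustive search", {
  p <- realize(fixture("parent"))
  u <- p$cone
  expect_true(fmap_equal(mediating_morphism(u, u), id_map(u$apex)))
  one <- fset("w", "W")
  c1 <- cat_cone(one,
                 list(left = fmap(one, p$spec$sets$left, c(w = "mare")),
                      right = fmap(one, p$spec$sets$right, c(w = "colt")),
                      constraint = fmap(one, p$spec$sets$constraint, c(w = "equine"))),
                 p$diagram)
  expect_identical(unname(mediating_morphism(c1, u)$assignment), "(mare,colt)")
  # random cone vs exhaustive filter of all candidate maps
  set.seed(909)
  X <- fset(c("s", "t"), "X")
  pick <- sample(u$apex$elements, 2, replace = TRUE)
  legs <- lapply(names(u$legs), function(n)
    fmap(X, u$legs[[n]]$cod,
         structure(unname(u$legs[[n]]$assignment[pick]), names = X$elements)))
  names(legs) <- names(u$legs)
  cX <- cat_cone(X, legs, p$diagram)
  m <- mediating_morphism(cX, u)
  survivors <- Filter(function(h) {
    all(vapply(names(u$legs), function(n)
      fmap_equal(compose(u$legs[[n]], h), cX$legs[[n]]), logical(1)))
  }, enumerate_maps(X, u$apex))
  expect_length(survivors, 1L)
  expect_true(fmap_equal(m, survivors[[1]]))
  # a non-cone has no factorization
  bad <- cat_cone(one,
                  list(left = fmap(one, p$spec$sets$left, c(w = "mare")),
                       right = fmap(one, p$spec$sets$right, c(w = "steer")),
                       constraint = fmap(one, p$spec$sets$constraint, c(w = "equine"))),
                  p$diagram, check = FALSE)
  expect_error(mediating_morphism(bad, u), class = "catsys_no_factorization")
})

test_that("verify_universal passes canonical cones, swapped products, and rejects corruptions", {
  p <- realize(fixture("parent"))
  expect_true(verify_universal(p$cone)$ok)
  # swapped-projection product over a discrete diagram is still a product
  A <- fset(c("John", "Mary"), "agents")
  pr <- product(A, A)
  d <- pr$diagram
  swapped <- cat_cone(pr$apex,
                      list(left = pr$legs$right, right = pr$legs$left), d)
  expect_true(verify_universal(swapped, d)$ok)
  # an apex with a duplicated element breaks uniqueness
  dup_apex <- fset(c(p$cone$apex$elements, "dup"), "P+dup")
  dup_legs <- lapply(p$cone$legs, function(leg) {
    asg <- leg$assignment
    asg[["dup"]] <- asg[["(mare,colt)"]]
    fmap(dup_apex, leg$cod, asg)
  })
  dup <- cat_cone(dup_apex, dup_legs, p$diagram)
  rep <- verify_universal(dup, p$diagram)
  expect_false(rep$ok)
  expect_true(any(vapply(rep$failures, function(f) f$factorizations >= 2, logical(1))))
})

test_that("limit enumeration respects the cap", {
  big <- fset(as.character(1:40), "big")
  d <- cat_diagram(discrete_shape(c("a", "b", "c")),
                   list(a = big, b = big, c = big))
  expect_error(limit(d, cap = 1000), class = "catsys_cap_exceeded")
})
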