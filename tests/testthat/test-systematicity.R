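# The cognitive-domain layer: realization styles, inference, membership
# diagnostics, quotients, architecture audits, block matrices.

test_that("the kinship pullback realizes exactly the licensed pairs", {
  p <- realize(fixture("parent"))
  expect_identical(p$apex$elements,
                   sort(c("(stallion,colt)", "(stallion,filly)", "(mare,colt)",
                          "(mare,filly)", "(bull,steer)", "(bull,heifer)",
                          "(cow,steer)", "(cow,heifer)"), method = "radix"))
  expect_true(check_commutative(p$diagram)$ok)
  expect_true(verify_universal(p$cone)$ok)
})

test_that("the refined triple realization distinguishes the two senses of calf", {
  pe <- realize(fixture("parent_extended"))
  expect_true("(whale,cetacean,calf)" %in% pe$apex$elements)
  both <- grepl("whale", pe$apex$elements) & grepl("steer", pe$apex$elements)
  expect_false(any(both))
  # constraint coordinate sits in the middle of each triple
  expect_identical(infer(pe, "species", c(progenitor = "whale")), "cetacean")
  expect_true(verify_universal(pe$cone)$ok)
})

test_that("role inference returns the printed fillers", {
  sq <- realize(fixture("square"))
  expect_identical(infer(sq, "square", c(root = "4")), "16")
  expect_identical(infer(sq, "root", c(square = "16", root = "4")), "4")
  lt <- realize(fixture("less_than"))
  expect_identical(infer(lt, "lesser", c(lesser = "2", greater = "3")), "2")
  p <- realize(fixture("parent"))
  expect_identical(infer(p, "progenitor", c(offspring = "colt", progenitor = "mare")),
                   "mare")
  expect_error(infer(p, "progenitor", c(offspring = "nonesuch")),
               class = "catsys_no_match")
  expect_error(infer(p, "progenitor", c(offspring = "colt")),
               class = "catsys_ambiguous_match")
})

test_that("membership distinguishes role-set from constraint violations, exhaustively", {
  p <- realize(fixture("parent"))
  m1 <- membership(p, c("stallion", "steer"))
  expect_false(m1$member); expect_identical(m1$reason, "constraint")
  m2 <- membership(p, c("colt", "mare"))
  expect_false(m2$member); expect_identical(m2$reason, "role_set")
  expect_true(membership(p, c("mare", "colt"))$member)
  expect_error(membership(p, c("unicorn", "colt")),
               class = "catsys_unknown_component")
  # every non-member over the component universe is classified
  comps <- c(p$spec$sets$left$elements, p$spec$sets$right$elements)
  for (a in comps) for (b in comps) {
    r <- membership(p, c(a, b))
    expect_true(r$reason %in% c("member", "role_set", "constraint"))
    expect_identical(r$member, tuple_label(a, b) %in% p$apex$elements)
  }
})

test_that("agreement fixtures license and forbid the right pairs", {
  sv <- realize(fixture("subject_verb"))
  expect_true(membership(sv, c("dogs", "chase"))$member)
  expect_true(membership(sv, c("cat", "chases"))$member)
  expect_false(membership(sv, c("dogs", "chases"))$member)
  sh <- realize(fixture("subject_verb_sheep"))
  expect_true("(sheep,sing,chases)" %in% sh$apex$elements)
  expect_true("(sheep,plur,chase)" %in% sh$apex$elements)
  pp <- realize(fixture("preposition"))
  expect_true(membership(pp, c("threw", "onto"))$member)
  expect_true(membership(pp, c("drenched", "none"))$member)
  expect_false(membership(pp, c("drenched", "onto"))$member)
  expect_false(membership(pp, c("threw", "none"))$member)
})

test_that("quotients are kernel-pair coequalizers isomorphic to the classifier image", {
  q <- realize(fixture("absolute"))
  expect_s3_class(q, "quotient_structure")
  expect_length(q$classes, 4L)
  cl3 <- q$classes[[which(vapply(q$classes, function(m) "3" %in% m, logical(1)))]]
  expect_setequal(cl3, c("3", "-3"))
  expect_true(is_isomorphism(q$image_iso)$is_iso)
  # injective classifier: all classes singletons
  A <- letters_set(4, "A")
  qi <- quotient(A, id_map(A))
  expect_true(all(lengths(qi$classes) == 1L))
  # grouping oracle on a wider window
  w <- fset(as.character(-4:4), "w")
  mags <- fset(as.character(0:4), "m")
  qa <- quotient(w, fn_fmap(w, mags, function(x) as.character(abs(as.integer(x)))))
  expect_length(qa$classes, 5L)
  oracle <- split(w$elements, vapply(w$elements, function(x)
    as.character(abs(as.integer(x))), character(1)))
  expect_identical(sort(unname(lengths(qa$classes))),
                   sort(unname(lengths(oracle))))
  expect_setequal(unlist(qa$classes), w$elements)
})

test_that("audit passes uniform architectures and pinpoints every swapped instance", {
  p <- realize(fixture("parent"))
  expect_true(audit(architecture(p))$ok)
  rep <- audit(architecture(p, swapped = c("(bull,steer)", "(bull,heifer)",
                                           "(cow,steer)", "(cow,heifer)")))
  expect_false(rep$ok)
  ce <- rep$counterexamples
  bs <- Filter(function(f) f$instance == "(bull,steer)" && f$role == "progenitor", ce)
  expect_length(bs, 1L)
  expect_identical(bs[[1]]$expected, "bull")
  expect_identical(bs[[1]]$produced, "steer")
  # loves: swapping the accessor on Mary-loves-John misreads John as the lover
  lv <- realize(fixture("loves"))
  repl <- audit(architecture(lv, swapped = "(Mary,John)"))
  expect_false(repl$ok)
  lover_ce <- Filter(function(f) f$role == "lover", repl$counterexamples)[[1]]
  expect_identical(lover_ce$expected, "Mary")
  expect_identical(lover_ce$produced, "John")
  # a swapped symmetric instance produces no counterexample
  expect_true(audit(architecture(lv, swapped = "(Mary,Mary)"))$ok)
  # counterexample set = exactly the swapped non-symmetric instances
  set.seed(333)
  swaps <- sample(lv$apex$elements, 5)
  repm <- audit(architecture(lv, swapped = swaps))
  hit <- unique(vapply(repm$counterexamples, function(f) f$instance, character(1)))
  nonsym <- Filter(function(x) {
    cc <- tuple_split(x)[[1]]; cc[1] != cc[2]
  }, swaps)
  expect_setequal(hit, nonsym)
  expect_error(architecture(p, swapped = "(colt,mare)"),
               class = "catsys_malformed_spec")
})

test_that("the block matrix shows diagonal blocks whose filled cells are the apex", {
  p <- realize(fixture("parent"))
  bm <- block_matrix(p)
  expect_identical(bm$filled, 8L)
  expect_length(bm$blocks, 2L)
  # cells outside the diagonal blocks are empty
  for (i in seq_len(nrow(bm$cells))) for (j in seq_len(ncol(bm$cells))) {
    if (bm$row_attr[i] != bm$col_attr[j]) expect_false(bm$cells[i, j])
  }
  # single shared attribute: the whole matrix is one full block
  A <- letters_set(2, "A"); B <- fset(c("x", "y"), "B"); one <- fset("*", "1")
  uni <- domain_spec("uni", "shared_constraint",
                     sets = list(left = A, right = B, constraint = one),
                     maps = list(left_attr = fn_fmap(A, one, function(x) "*"),
                                 right_attr = fn_fmap(B, one, function(x) "*")),
                     roles = c(l = "left", r = "right"))
  bmu <- block_matrix(realize(uni))
  expect_true(all(bmu$cells))
  # seeded random domain: filled cells = apex size
  rd <- realize(random_domain(synth_config(99)))
  expect_identical(block_matrix(rd)$filled, length(rd$apex$elements))
  expect_error(block_matrix(realize(fixture("loves"))),
               class = "catsys_wrong_style")
})

test_that("malformed domain specs are rejected with the violated requirement named", {
  A <- letters_set(2, "A")
  expect_error(domain_spec("x", "nosuch", sets = list()),
               class = "catsys_malformed_spec")
  expect_error(domain_spec("x", "shared_constraint",
                           sets = list(left = A, right = A, constraint = A)),
               regexp = "left_attr", class = "catsys_malformed_spec")
  expect_error(domain_spec("x", "characteristic",
                           sets = list(left = A, right = A)),
               regexp = "relation", class = "catsys_malformed_spec")
  expect_error(domain_spec("x", "quotient", sets = list(base = A)),
               regexp = "classifier", class = "catsys_malformed_spec")
})
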