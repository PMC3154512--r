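# Fixture catalog: every worked cognitive-domain example as a ready-made
# domain_spec, plus a seeded random-domain generator so that all property
# suites run without external data. Integer-based domains use explicit
# finite windows (roots [-5,5] with squares [0,25]; less-than over {0..9};
# absolute over {-3..3}) chosen to contain every worked instance.

int_labels <- function(lo, hi) as.character(seq.int(lo, hi))

fixture_builders <- function() list(
  loves = function() {
    agents <- c("John", "Mary", "Sue", "Tom")
    domain_spec("loves", "product",
                sets = list(left = fset(agents, "agents"),
                            right = fset(agents, "agents")),
                roles = c(lover = "left", beloved = "right"))
  },
  parent = function() {
    Pr <- fset(c("stallion", "mare", "bull", "cow"), "progenitors")
    O <- fset(c("colt", "filly", "steer", "heifer"), "offspring")
    S <- fset(c("equine", "bovine"), "species")
    domain_spec("parent", "shared_constraint",
                sets = list(left = Pr, right = O, constraint = S),
                maps = list(
                  left_attr = fmap(Pr, S, c(stallion = "equine", mare = "equine",
                                            bull = "bovine", cow = "bovine"),
                                   name = "species_of_progenitor"),
                  right_attr = fmap(O, S, c(colt = "equine", filly = "equine",
                                            steer = "bovine", heifer = "bovine"),
                                    name = "species_of_offspring")),
                roles = c(progenitor = "left", offspring = "right",
                          species = "constraint"))
  },
  parent_extended = function() {
    lp <- c(tuple_label("stallion", "equine"), tuple_label("mare", "equine"),
            tuple_label("bull", "bovine"), tuple_label("cow", "bovine"),
            tuple_label("whale", "cetacean"))
    rp <- c(tuple_label("equine", "colt"), tuple_label("equine", "filly"),
            tuple_label("bovine", "steer"), tuple_label("bovine", "heifer"),
            tuple_label("bovine", "calf"), tuple_label("cetacean", "calf"))
    L <- fset(lp, "parent_species_pairs")
    R <- fset(rp, "species_offspring_pairs")
    S <- fset(c("equine", "bovine", "cetacean"), "species")
    second <- function(x) vapply(tuple_split(x), `[[`, character(1), 2L)
    first <- function(x) vapply(tuple_split(x), `[[`, character(1), 1L)
    domain_spec("parent_extended", "refined_triple",
                sets = list(left_pairs = L, right_pairs = R, constraint = S),
                maps = list(
                  left_attr = fmap(L, S, structure(second(L$elements),
                                                   names = L$elements),
                                   name = "pair_species"),
                  right_attr = fmap(R, S, structure(first(R$elements),
                                                    names = R$elements),
                                    name = "species_pair")),
                roles = c(progenitor = "left", species = "constraint",
                          offspring = "right"))
  },
  square = function() {
    roots <- int_labels(-5, 5)
    squares <- int_labels(0, 25)
    rel <- lapply(seq.int(-5, 5), function(r)
      c(as.character(r), as.character(r * r)))
    domain_spec("square", "characteristic",
                sets = list(left = fset(roots, "roots"),
                            right = fset(squares, "squares")),
                roles = c(root = "left", square = "right"),
                relation = rel)
  },
  absolute = function() {
    base <- fset(int_labels(-3, 3), "window")
    mags <- fset(int_labels(0, 3), "magnitudes")
    asg <- structure(as.character(abs(seq.int(-3, 3))),
                     names = int_labels(-3, 3))
    domain_spec("absolute", "quotient",
                sets = list(base = base, magnitudes = mags),
                maps = list(classifier = fmap(base, mags, asg, name = "abs")))
  },
  less_than = function() {
    w <- int_labels(0, 9)
    rel <- list()
    for (a in 0:9) for (b in 0:9) if (a < b) {
      rel[[length(rel) + 1L]] <- c(as.character(a), as.character(b))
    }
    domain_spec("less_than", "characteristic",
                sets = list(left = fset(w, "numbers"),
                            right = fset(w, "numbers")),
                roles = c(lesser = "left", greater = "right"),
                relation = rel)
  },
  subject_verb = function() {
    N <- fset(c("dog", "dogs", "cat", "cats"), "nouns")
    V <- fset(c("chase", "chases"), "verbs")
    A <- fset(c("sing", "plur"), "number")
    domain_spec("subject_verb", "shared_constraint",
                sets = list(left = N, right = V, constraint = A),
                maps = list(
                  left_attr = fmap(N, A, c(dog = "sing", dogs = "plur",
                                           cat = "sing", cats = "plur"),
                                   name = "noun_number"),
                  right_attr = fmap(V, A, c(chase = "plur", chases = "sing"),
                                    name = "verb_number")),
                roles = c(subject = "left", verb = "right",
                          number = "constraint"))
  },
  subject_verb_sheep = function() {
    lp <- c(tuple_label("dog", "sing"), tuple_label("dogs", "plur"),
            tuple_label("cat", "sing"), tuple_label("cats", "plur"),
            tuple_label("farmer", "sing"),
            tuple_label("sheep", "sing"), tuple_label("sheep", "plur"))
    rp <- c(tuple_label("sing", "chases"), tuple_label("plur", "chase"))
    L <- fset(lp, "noun_number_pairs")
    R <- fset(rp, "number_verb_pairs")
    A <- fset(c("sing", "plur"), "number")
    second <- function(x) vapply(tuple_split(x), `[[`, character(1), 2L)
    first <- function(x) vapply(tuple_split(x), `[[`, character(1), 1L)
    domain_spec("subject_verb_sheep", "refined_triple",
                sets = list(left_pairs = L, right_pairs = R, constraint = A),
                maps = list(
                  left_attr = fmap(L, A, structure(second(L$elements),
                                                   names = L$elements),
                                   name = "pair_number"),
                  right_attr = fmap(R, A, structure(first(R$elements),
                                                    names = R$elements),
                                    name = "number_pair")),
                roles = c(subject = "left", number = "constraint",
                          verb = "right"))
  },
  preposition = function() {
    V <- fset(c("dripped", "threw", "poured", "tossed",
                "dampened", "drenched", "wet"), "verbs")
    P <- fset(c("onto", "over", "none"), "prepositions")
    A <- fset(c("prep", "noprep"), "requirement")
    domain_spec("preposition", "shared_constraint",
                sets = list(left = V, right = P, constraint = A),
                maps = list(
                  left_attr = fmap(V, A, c(dripped = "prep", threw = "prep",
                                           poured = "prep", tossed = "prep",
                                           dampened = "noprep",
                                           drenched = "noprep", wet = "noprep"),
                                   name = "verb_requirement"),
                  right_attr = fmap(P, A, c(onto = "prep", over = "prep",
                                            none = "noprep"),
                                    name = "prep_requirement")),
                roles = c(verb = "left", preposition = "right",
                          requirement = "constraint"))
  }
)

#' Names of the fixture catalog
#'
#' @return Character vector of available fixture names.
#' @export
fixture_names <- function() names(fixture_builders())

#' Retrieve a catalog fixture
#'
#' The catalog ships every worked cognitive-domain example as a ready-made
#' [domain_spec()]: `loves` (full product of four agents), `parent`
#' (shared-constraint pullback over species), `parent_extended` (triple
#' pullback distinguishing the two senses of *calf*), `square` and
#' `less_than` (characteristic-map pullbacks over integer windows),
#' `absolute` (kernel-pair quotient of the absolute-value map),
#' `subject_verb` (third-person agreement), `subject_verb_sheep` (number
#' ambiguity of *sheep*), and `preposition` (verb-preposition selection).
#' Each call builds a fresh copy.
#'
#' @param name fixture name, one of [fixture_names()].
#' @return A [domain_spec()].
#' @examples
#' realize(fixture("parent"))$apex
#' @export
fixture <- function(name) {
  builders <- fixture_builders()
  cs_assert(name %in% names(builders), "catsys_unknown_fixture",
            sprintf("unknown fixture '%s'; available: %s", name,
                    paste(names(builders), collapse = ", ")))
  builders[[name]]()
}

#' Configuration for the random-domain generator
#'
#' @param seed integer seed of the portable congruential generator.
#' @param n_left,n_right,n_constraint set sizes (defaults 6, 6, 3 — desk
#'   scale, comparable to the catalog fixtures).
#' @param forced_empty_block when `TRUE`, the right attribute map avoids the
#'   first constraint value, forcing at least one empty block.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed, n_left = 6, n_right = 6, n_constraint = 3,
                         forced_empty_block = FALSE) {
  cs_assert(n_left >= 0 && n_right >= 0 && n_constraint >= 0,
            "catsys_malformed_spec", "sizes must be non-negative")
  structure(list(seed = as.integer(seed), n_left = as.integer(n_left),
                 n_right = as.integer(n_right),
                 n_constraint = as.integer(n_constraint),
                 forced_empty_block = isTRUE(forced_empty_block)),
            class = "synth_config")
}

#' Generate a seeded random shared-constraint domain
#'
#' Attribute values are assigned independently and uniformly over the
#' constraint set using a portable Park-Miller congruential generator, so
#' the same seed yields byte-identical domains in any environment. Under
#' uniform assignment the expected apex size is
#' `n_left * n_right / n_constraint`.
#'
#' @param cfg a [synth_config()].
#' @return A [domain_spec()] of style `shared_constraint`.
#' @export
random_domain <- function(cfg) {
  cs_assert(inherits(cfg, "synth_config"), "catsys_malformed_spec",
            "random_domain expects a synth_config")
  cs_assert(cfg$n_constraint > 0L || (cfg$n_left == 0L && cfg$n_right == 0L),
            "catsys_malformed_spec",
            "an empty constraint set admits no attribute maps from nonempty sides")
  lab <- function(prefix, n) if (n == 0L) character(0) else
    sprintf("%s%03d", prefix, seq_len(n))
  L <- fset(lab("l", cfg$n_left), "left")
  R <- fset(lab("r", cfg$n_right), "right")
  C <- fset(lab("c", cfg$n_constraint), "constraint")
  rng <- lcg_new(cfg$seed)
  draw <- function(n) {
    out <- character(n)
    for (i in seq_len(n)) {
      res <- lcg_int(rng, cfg$n_constraint)
      rng <<- res$rng
      out[i] <- C$elements[res$value]
    }
    out
  }
  la <- draw(cfg$n_left)
  ra <- draw(cfg$n_right)
  if (cfg$forced_empty_block && cfg$n_constraint >= 2L && cfg$n_right > 0L) {
    ra[ra == C$elements[1]] <- C$elements[2]
  }
  domain_spec(sprintf("random_%d", cfg$seed), "shared_constraint",
              sets = list(left = L, right = R, constraint = C),
              maps = list(
                left_attr = fmap(L, C, structure(la, names = L$elements),
                                 name = "left_attr"),
                right_attr = fmap(R, C, structure(ra, names = R$elements),
                                  name = "right_attr")),
              roles = c(lhs = "left", rhs = "right", tag = "constraint"))
}
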