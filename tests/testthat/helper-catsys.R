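# Shared test fixtures: deterministic random maps and small comprehension
# oracles, all generated in code at test time.

# A uniformly random total map dom -> cod (caller controls the RNG seed).
random_fmap <- function(dom, cod, name = "rnd") {
  fmap(dom, cod,
       structure(sample(cod$elements, fset_size(dom), replace = TRUE),
                 names = dom$elements),
       name = name)
}

# Build an fmap from an R function acting on labels.
fn_fmap <- function(dom, cod, f, name = "fn") {
  fmap(dom, cod, structure(vapply(dom$elements, f, character(1)),
                           names = dom$elements), name = name)
}

# Independent double-loop oracle for a pullback apex.
comprehension_pullback <- function(f, g) {
  out <- character(0)
  for (a in f$dom$elements) for (b in g$dom$elements) {
    if (f$assignment[[a]] == g$assignment[[b]]) {
      out <- c(out, tuple_label(a, b))
    }
  }
  sort(out, method = "radix")
}

letters_set <- function(n, name = "A") fset(head(letters, n), name)
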