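---
title: "Verified universal constructions for quasi-systematic domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verified universal constructions for quasi-systematic domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catsys)
```

## The model

`catsys` works in the category of finite sets: objects are finite sets of
opaque string labels (`fset`), morphisms are total functions between them
(`fmap`), compared extensionally — two maps are equal when they have the
same domain elements, codomain elements and assignment; display names never
enter equality. Everything else is built from this ambient category:

* **Diagrams** place sets on the nodes and maps on the edges of a finite
  shape graph. Commutativity is checked by enumerating directed paths and
  comparing composite maps element-wise; a failing pair of paths is
  reported with a witnessing element.
* **Universal constructions** come in canonical form — product, pullback,
  equalizer, their duals, and generic limits/colimits over any finite
  diagram — and each canonical cone carries a closure mapping a family of
  leg values to its apex label, which makes the mediating morphism directly
  computable rather than searched for.
* **Verification** is the point. `verify_universal()` does not trust the
  canonical constructions: it enumerates, for each probe apex, *every* cone
  over the diagram and counts the mediating maps into the candidate,
  requiring exactly one. `verify_adjunction()` does the same for the
  diagonal–product adjunction: functor laws, unit naturality, the
  factorization through the accessors (counit side), the transpose through
  the unit, and both triangle identities, all by exhaustive enumeration.

The cognitive-domain layer realizes a declared relation in one of five
styles. A `shared_constraint` domain is the pullback of two attribute maps
into a common constraint set (kinship over species, subject–verb agreement
over number, verb–preposition selection over a requirement flag). A
`refined_triple` domain pulls back two *pair* sets over their shared
coordinate, producing triples — this is what separates the two senses of an
ambiguous term, such as a calf born to cattle versus to whales, or the noun
*sheep* used in the singular and the plural. A `characteristic` domain
handles an arbitrary relation as the pullback of its characteristic map
along the truth inclusion — the subobject-classifier pattern — which is
required when the relation is not the graph of a function (less-than). A
`product` domain is the unconstrained special case (a pullback over a
singleton constraint collapses to it, which the tests confirm), and a
`quotient` domain is the kernel-pair coequalizer of a classifier map.

The audit criterion operationalizes systematicity element-wise: an
architecture (a per-instance choice of canonical or swapped accessors)
passes exactly when every instance's accessors agree with the canonical
mediating projections. This is the executable restatement of the
uniqueness half of the universal property — a mixed architecture is one
that does not factor through the single mediating construction, and the
audit reports each disagreeing instance with the expected and produced role
fillers.

## Parameters that matter

* **Enumeration cap** (`cap`, default $10^6$ candidate maps or cones,
  overridable everywhere and as `--max-enum` on the command line).
  Exhaustive verification over finite sets is exponential by nature
  (`enumerate_maps(A, B)` has $|B|^{|A|}$ elements); the cap keeps every
  search at desk scale and turns an over-budget request into a
  `catsys_cap_exceeded` error that reports the count that would have been
  required, rather than an open-ended computation.
* **Probe apexes** (`default_probes()`): all sets of sizes 0, 1 and 2 over
  a fixed two-letter alphabet. Quantifying over *all* objects is
  impossible; sizes up to two already separate the failure modes that
  matter — size 1 detects existence failures, size 2 detects uniqueness
  failures — for every construction in scope. Callers may supply larger
  probes where they want more assurance.
* **Path bound** (`max_path_len`, default 8): commutativity compares
  composites along paths up to this many edges. Every diagram the package
  constructs has diameter well under 8; cyclic shapes require a finite
  bound explicitly.
* **Integer windows**: formal relations over the integers are realized on
  declared finite windows — square roots over $[-5, 5]$ with squares over
  $[0, 25]$, less-than over $\{0..9\}$, absolute value over $\{-3..3\}$.
  The windows are chosen to contain every worked instance while keeping
  the characteristic-map product (at most $10 \times 10$ here) cheap to
  verify exhaustively; they are the package's own finitization, declarable
  per spec file via the `windows` field.

## The synthetic generator

`random_domain()` draws a `shared_constraint` domain whose attribute values
are assigned independently and uniformly over the constraint set, using a
Park–Miller linear congruential generator ($x \mapsto 16807x \bmod
2^{31}-1$) rather than R's RNG, so the same seed reproduces the same domain
byte-for-byte in any environment or language. Default sizes are 6 left
elements, 6 right elements, 3 constraint values — the same order of
magnitude as the catalog fixtures. Under this model the expected apex size
is $nm/k$, which the test suite checks over 500 seeds within three
standard errors.

What the generator emulates is the *structure* of a quasi-systematic
domain: two typed lexicons tied by a shared attribute, with blocks of
freely combining instances. What it does not emulate: naturalistic token
frequencies, graded or probabilistic acceptability, attribute maps with
dependence between the two sides, or lexicons large enough that exhaustive
verification would be infeasible. Passing the property suites therefore
shows that the constructions are correct on uniformly structured finite
domains; it says nothing about corpus-scale coverage, and nothing about
domains whose constraints are not expressible as a finite attribute map.

## Numerical and representational choices

* Elements are opaque strings; tuples are encoded as `"(x,y)"` /
  `"(x,y,z)"` with no whitespace, so nested constructions (pairs of pairs)
  remain ordinary labels. Splitting is nesting-aware.
* All element collections are kept in byte-lexicographic (radix) order,
  which is locale-independent; every enumeration, apex, report and CLI
  output inherits this order, making runs byte-identical.
* Map enumeration is in dictionary order over assignments with the first
  domain element most significant.
* Empty-set conventions: exactly one map out of the empty set; none into
  it from a nonempty one. The empty-shape limit is the terminal singleton
  `"()"`.
* Quotient classes are labelled by their lexicographically least member
  (a member's label, not a set literal), which keeps class labels stable
  and human-readable; colimit and pushout elements are tagged with their
  node of origin before quotienting.
* In `refined_triple` apexes the constraint coordinate is the middle
  coordinate of each triple, matching how parent–species–offspring
  triples read.
* The truth object is `{"false", "true"}` with the inclusion picking
  `"true"`; characteristic-style apexes are presented as the bare relation
  pairs rather than the pair-with-unit encoding the pullback produces
  internally.

## Design choices where the design was open

* **Unit and counit formulas.** The unit `a ↦ (a, a)` and counit
  `(p₁, p₂)` are adopted as the standard formulas; they are uniquely
  forced by the universal property, and `verify_adjunction()` confirms
  that independently rather than taking the formulas on trust.
* **Pullback adjunction.** The limit-side adjunction for sink diagrams is
  verified through the universal-morphism property of the sink limit
  (`verify_universal()` plus the limit–pullback isomorphism), not through
  a separate functor-category construction; the inner composite morphism
  of the simplified square presentation is always reconstructed and
  checked rather than omitted.
* **Quotient realization.** The absolute-value domain is built as the
  kernel-pair coequalizer of the classifier, whose apex is verified to be
  isomorphic to the classifier's image — equivalent to the pushout
  presentation, as the pushout/coequalizer agreement test shows.
* **Selectors.** `infer()` selectors are equality constraints on role
  values only, which keeps inference total and decidable; richer
  predicates would reintroduce an evaluation language the package does not
  need.
* **CLI.** Flags are parsed by hand (a dependency-free loop); `--swap`
  values are split only at top-level commas so instance labels like
  `"(bull,steer)"` survive intact.

## Problem sizes

The shipped verification runs are all desk-scale by construction: catalog
fixtures have 2–45 instances; the largest exhaustive search is the
universal-property check for the less-than characteristic pullback (a
$100$-element product, $10^4$ candidate leg assignments per size-2 probe);
property suites use 200 seeded random pullbacks on $5 \times 5 \times 3$
domains and 500 seeds for the apex-size concentration check. The whole
suite runs in well under a minute per module on one core.

## Known limitations

* Only the category of finite sets: no enriched, weighted, or
  higher-categorical structure, no infinite shapes, no partial maps or
  relations-as-morphisms.
* Universal properties are verified on finite probe families, not proved;
  probes of size ≤ 2 are sufficient for the failure modes of the
  constructions in scope, but a deliberately pathological candidate could
  in principle require larger probes.
* Agreement domains are confined to third-person agreement, and the
  preposition domain records which verbs select a preposition, not why.
* Integer-based relations exist only on their declared windows; inference
  outside a window is an `unknown component` error, not an extrapolation.
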