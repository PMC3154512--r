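# catsys

A finite category theory engine for building and *auditing* relational
cognitive architectures.

## The problem

Human cognitive capacities come in structurally related groups: whoever can
infer *mare* as the progenitor from the proposition *mares parent colts* can
also infer *bull* from *bulls parent heifers* — but nobody concludes that
*stallions parent steers*. This is **quasi-systematicity**: the licensed
combinations of constituents are constrained by shared structure (here, a
common species), and the capacities over the licensed instances stand or
fall together. A compositional architecture explains this only if its
accessors are forced to agree across all instances; an architecture free to
read components one way on some instances and another way on others makes
no such prediction.

Category theory makes the "forced to agree" part precise. A relation with a
shared constraint is a **pullback**: given attribute maps
`f : Pr → S` and `g : O → S`, the pullback object is

    Pr ×_S O = { (a, b) ∈ Pr × O : f(a) = g(b) }

with coordinate projections `p₁`, `p₂`. The pullback is a **limit**: any
competitor cone factors through it via exactly one mediating morphism, so
there is one and only one accessor scheme compatible with all instances.
The unconstrained case is the **product** `A × B`, the right adjoint of the
pair diagonal functor `Δ : A ↦ (A, A)` with unit `η : a ↦ (a, a)` and
counit `(p₁, p₂)`; relations that are not attribute-determined arise as the
pullback of their characteristic map `χ : A × B → Ω` along
`true : 1 → Ω`; merged instances (e.g. `3` and `-3` under *absolute*) arise
as kernel-pair coequalizers.

`catsys` implements all of these constructions over finite sets of opaque
string labels and — the point of the package — *verifies* them
exhaustively on probe objects: commutativity of every diagram,
existence-and-uniqueness of mediating morphisms, functor laws, naturality,
triangle identities, and the hom-set bijection
`Hom(ΔA, (B₁,B₂)) ≅ Hom(A, B₁×B₂)`. Deliberately broken candidates (swapped
or mixed accessors, degenerate units) are constructible, and the verifiers
report the counterexamples.

## Worked example

```r
library(catsys)
p <- realize(fixture("parent"))
print(p)
#> realized relation 'parent' (style shared_constraint): 8 instance(s)
#>   apex: { (bull,heifer), (bull,steer), (cow,heifer), (cow,steer),
#>           (mare,colt), (mare,filly), (stallion,colt), (stallion,filly) }
#>   roles: progenitor, offspring, species
```

The apex holds exactly the eight licensed pairs — equine with equine,
bovine with bovine. Role inference and membership behave accordingly:

```r
infer(p, "progenitor", c(offspring = "colt", progenitor = "mare"))
#> [1] "mare"
membership(p, c("stallion", "steer"))$reason   # wrong species
#> [1] "constraint"
membership(p, c("colt", "mare"))$reason        # wrong sides entirely
#> [1] "role_set"
```

The block-matrix view shows the instances as diagonal blocks, one per
shared species:

```r
print(block_matrix(p))
#>          | heifer steer colt filly
#> ----------------------------------
#>     bull |      x     x    .     .
#>      cow |      x     x    .     .
#> ----------------------------------
#>     mare |      .     .    x     x
#> stallion |      .     .    x     x
#> 8 filled cell(s) in 2 diagonal block(s)
```

An architecture that reads the bovine instances with swapped accessors
fails the audit exactly where it should:

```r
audit(architecture(p, swapped = "(bull,steer)"))$counterexamples[[1]]
#> $instance: "(bull,steer)"  $role: "progenitor"
#> $expected: "bull"          $produced: "steer"
```

And the universal property itself is checked by exhaustive search over
probe cones:

```r
verify_universal(p$cone)$ok
#> [1] TRUE
verify_adjunction()$ok                                  # diagonal ⊣ product
#> [1] TRUE
verify_adjunction(right = swapped_product_functor())$ok # unit unchanged
#> [1] FALSE
```

Nine fixtures ship with the package (`fixture_names()`): the *loves*
product, the *parent* pullback and its triple-refined extension, the
*square*, *less-than* and *absolute* formal relations over declared integer
windows, subject–verb agreement with and without the number-ambiguous
*sheep*, and verb–preposition selection.

## Command line

```sh
inst/cli/catsys demo                                    # run every fixture end-to-end
inst/cli/catsys build  --fixture parent
inst/cli/catsys audit  --fixture parent --swap "(bull,steer)"   # exit 1
inst/cli/catsys render --fixture parent --format json
inst/cli/catsys verify --spec my_domain.json
```

Domains are declared in a small JSON dialect (sets, maps, roles, style;
see `write_domain_spec()` / `read_domain_spec()`); integer windows such as
`{"left": [-5, 5]}` are materialized into label sets at read time.

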