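# Model-definition format (v1)

Line-oriented UTF-8 text; `#` starts a comment; blank lines ignored.
Sections begin with `@<name>` headers and may appear in any order.

```
file        := { section }
section     := "@compartments" { ident... }
             | "@metabolites"  { metabolite-line }
             | "@enzymes"      { enzyme-line }
             | "@reactions"    { reaction-line }
             | "@branches"     { branch-line }
             | "@sources"      { source-line }
             | "@genes"        { gene-line }
             | "@tf"           { tf-line }
             | "@switches"     { switch-line }

metabolite-line := id compartment
enzyme-line     := id compartment [ "gene=" gene-id ] [ "kdeg=" number ]
reaction-line   := id ":" species "->" species [ "|" opts ]
                   opts := [ "enzyme=" enzyme-id ] [ "r=" number ] [ "w=" number ]
species         := term { "+" term } ;  term := [ number "*" ] metabolite-id
branch-line     := parent-id ":" child "=" fraction { child "=" fraction }
                   child := reaction-id | "sink"        # fractions sum to 1
source-line     := metabolite-id [ number ]              # baseline influx phi
gene-line       := id ( "enzyme=" enzyme-id | "protein=" protein-id )
                   [ "kd=" number ] [ "kdp=" number ]
tf-line         := regulator-id "->" gene-id sign
                   [ "Qmax=" number ] [ "Qhat=" number ]
                   [ "hill=" number ] [ "basal=" number ]
                   sign := "+" | "-"
switch-line     := id ":" [ "act=" state-ids ] [ "inh=" state-ids ]
                   [ "ka=" number ] [ "kd=" number ]
                   state-ids := id { "," id }            # driver = mean level
```

Semantics:

* Compartments must come from `liver, adipose, blood, pancreas, peripheral,
  macrophage`.
* A reaction without `enzyme=` is a carrier-free transport step (first-order
  in its substrates).
* Branch children consume the parent as their first-listed substrate; the
  reserved child `sink` is a first-order export route. Declared fractions
  split the parent efflux remaining after secondary-substrate draws.
  Metabolites with no consumers receive an automatic sink.
* A gene produces an mRNA state named by the gene id. `enzyme=` targets
  drive that enzyme's synthesis; `protein=` targets create a protein state.
* A switch `x` creates states `x_a` (active) and `x_i` (inactive), both 1 at
  baseline; its inactivation factor and synthesis flux are derived so the
  baseline is an exact fixed point.
* State ids referenced by `@tf` regulators and switch drivers may be any
  state: metabolite, enzyme, mRNA (gene id), protein, or switch pool.
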