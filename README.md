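# reefar

Bioeconomic modelling of an artificial reef (AR) deployed inside a no-take
zone, surrounded by an open-access fishing area — including the illegal
fishing that real no-take zones experience.

## The problem

Artificial reefs are deployed both to *produce* fish (extra habitat
capacity) and to *attract* them. When the reef sits in a no-take zone, the
concentrated biomass spills over to the surrounding fishery — but it also
invites poaching. `reefar` is for fisheries modellers and marine-ecology
researchers who want to explore how reef volume, attraction and production
strength, and the illegal-effort fraction jointly set the equilibrium
catch and its split between legal and illegal fishers.

## The model

Two patches: no-take zone (capacity `K1 = alpha*K + V*delta_k`, the reef's
production effect) and fishing area (`K2 = (1-alpha)*K`). Fish move fast
toward an ideal free distribution perturbed by a reef attraction function
`beta(V)`; a fraction `gamma` of total effort fishes illegally on the
reef. Slow dynamics are logistic growth plus open-access (Gordon–Schaefer)
effort adjustment. Aggregating over the fast timescale gives the reduced
system for total biomass `n` and effort `E`:

    dn/dt = r n (1 - nu1*^2 n / K1 - (1-nu1*)^2 n / K2) - q Q n E
    dE/dt = (p q Q n - c) E

with `nu1* = B/(A+B)` (`A = a/K1`, `B = a/K2 + beta(V)`) the
fast-equilibrium biomass share on the reef and
`Q = gamma*nu1* + (1-gamma)*(1-nu1*)`. The bionomic equilibrium is closed
form: `n* = c/(p q Q)`, `E* = r (1 - n*/K_eff) / (q Q)`, with catch split
into reef and fishing-area components. Reef catch overtakes fishing-area
catch exactly at `gamma = 1 - nu1*`.

## Worked example

```r
library(reefar)
m <- reef_model(beta0 = 1, delta_k = 5, V = 120, gamma = 0.05)
summary(m)
```

```
Artificial-reef fishery model -- equilibrium summary
...
Derived quantities:
  K1 = 620  K2 = 80  beta(V) = 0.025  nu1* = 0.9394

Reduced-model equilibrium (viable fishery)
  nu1* = 0.9394  Q = 0.1045  K_eff = 680.6
  n* = 9.565  E* = 4.715
  catch: total = 4.715  reef = 2.119  fishing area = 2.597
Reef catch overtakes fishing-area catch at gamma = 0.06061 (6%)
```

Read: a 120 m³ reef with strong production (`delta_k = 5`) and attraction
(`beta0 = 1`) holds 93.9 % of the fish biomass in the no-take zone. With
5 % of the effort fishing illegally, the fishery is viable, the
equilibrium stock is 9.57 tons, and the 4.72 tons/unit-time equilibrium
catch already comes 45 % from poaching; past 6 % illegal effort the reef
yields more catch than the entire legal fishing area.

Scenario tables and finders:

```r
tab <- run_preset("fig2b")                       # catch vs gamma at 120 m^3
find_optimal_volume(reef_params(beta0 = 1, delta_k = 5),
                    gamma = 0, V_bracket = c(0, 600))
#> $verdict
#> [1] "monotone increasing"   # no interior optimum under this attraction form
annulus_width(500, 0.2)
#> [1] 618.0339887             # fishing ring width for a 500 m no-take zone
```

A thin command-line interface wraps the same functions:

```sh
Rscript exec/reefar sweep-gamma --preset fig2b --out fig2b.csv
Rscript exec/reefar geometry --radius 500 --alpha 0.2
```

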