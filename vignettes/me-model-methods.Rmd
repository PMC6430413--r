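---
title: "Coupled metabolism and expression modeling for a toy acetogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled metabolism and expression modeling for a toy acetogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetome)
```

# The model

`acetome` implements a metabolism-and-expression (ME) model: a
constraint-based model in which macromolecule amounts are decision
variables tied to metabolic fluxes through the growth rate $\mu$. The
metabolic side is an ordinary stoichiometric network at steady state,
$S\,v = 0$ with flux bounds. The expression side adds transcription,
translation, mRNA turnover, complex assembly with metal-cofactor
delivery, and membrane translocation as explicit reactions, and couples
them to catalysis:

* an enzyme-catalyzed flux $v_r$ consumes its complex at
  $\mu\,v_r/(3600\,k_\mathrm{eff})$ — the steady-state amount of catalyst
  needed, $v_r/(3600\,k_\mathrm{eff})$, diluted by growth;
* translation of a protein of length $L$ occupies ribosomes at
  $\mu L/(3600\,k_\mathrm{rib})$ and its mRNA at
  $(\mu + k_\mathrm{deg})/k_\mathrm{tl}$ per event, the degraded share
  returning to the NMP pool through an explicit degradation reaction;
* the biomass-dilution row fixes total macromolecule mass production to
  $\mu \times 1\,\mathrm{g\,gDW^{-1}}$, with fixed demands for DNA,
  murein, lipid (cardiolipin) and a generic "other" fraction, protein
  filling the remainder;
* the unmodeled-protein row pins the mass of a generic stand-in protein
  to $f/(1-f)$ times the modeled proteome ($f = 0.35$ by default).

Every coefficient is affine in $\mu$ ($a + b\mu$), so fixing $\mu$ gives
a linear program. Growth maximization is bisection over LP feasibility:
the feasible set is down-closed in $\mu$, and `maximize_growth()`
brackets the boundary to `mu_tol` (default $10^{-6}\,h^{-1}$). The final
solve minimizes total expression flux, selecting a parsimonious
representative among alternate optima; this is a reporting convention,
not a uniqueness claim.

Turnover defaults to $k_\mathrm{eff} = 25\,s^{-1}$, the acetogen-average
turnover rate this parameterization adopts for every enzyme; machinery
rates are conventional bacterial values (RNA polymerase 55 nt/s,
ribosome 12 aa/s, 300 translation initiations per mRNA per hour, mRNA
half-life of about 5 minutes), all config-overridable through
`coupling_params()`. GAM and NGAM default to 45 mmol ATP/gDW and
0.45 mmol ATP/gDW/h. Polymerization energetics follow textbook costs: two
phosphate bonds per transcribed nucleotide, four ATP equivalents per
translated residue (two for charging, two GTP-as-ATP for elongation),
and one ATP per started 25-residue segment during translocation
(ceiling rule, so the 26-residue dummy protein costs 2).

## Cofactor delivery

Modified complexes draw their cofactors through explicit pathways:
nickel is loaded onto a Hyp carrier (the loading reaction is catalyzed
by the Hyp machinery itself) and transferred during complex formation;
iron-sulfur clusters are built on a NifU-like scaffold from
4 Fe$^{2+}$ + 4 sulfide with IscS sulfur donation and SufBC catalysis,
then transferred by ErpA; simple cofactors (cobalt for the
methyltransferase corrinoid, magnesium for the rRNA/tRNA modification
stand-ins) are consumed directly. Because delivery is mass-balanced,
metal uptake at any solution equals exactly the metal content of the
complexes formed.

Ferredoxin and thioredoxin are proteins that appear chemically as
metabolite redox pairs; without extra coupling they would carry flux
while never being expressed. Every reaction producing the reduced form
therefore carries a usage coupling of $\mu/(3600\,k_\mathrm{eff})$ on
the carrier complex.

# The toy acetogen

The synthetic organism is a CO / CO$_2$+H$_2$ / fructose-fed acetogen
with the Wood-Ljungdahl pathway (WLP): CO oxidation (CODH4), a
formate/methyl branch (lumped methylene synthesis, MTHFR5, the
corrinoid methyltransferase METR), acetyl-CoA synthase (CODH_ACS,
2 nickels), acetate kinase lump, the AOR + alcohol-dehydrogenase
ethanol route, Rnf + ATP synthase energy conservation (2 protons
pumped per ferredoxin, 4 per ATP), two hydrogenases (the bifurcating
HYDFDN2r and the nickel HYD2), the Nfn transhydrogenase, lumped
glycolysis, and a cardiolipin branch whose synthase releases glycerol,
recyclable through glycerol dehydrogenase + dihydroxyacetone kinase or
secreted. Two immutable net balances anchor the stoichiometry and are
verified by row reduction in the tests:

$$4\,\mathrm{CO} + 2\,\mathrm{H_2O} \rightarrow \mathrm{acetate} + 2\,\mathrm{CO_2}
\qquad
6\,\mathrm{CO} + 3\,\mathrm{H_2O} \rightarrow \mathrm{ethanol} + 4\,\mathrm{CO_2}$$

All small molecules carry real formulas and charges; macromolecules and
lumped biomass constituents get pseudo-formulas derived mechanically as
monomer sums minus one water per bond (or directly from their defining
reaction), so `check_balances()` closes every reaction exactly. The
$\mu$-proportional coupling terms are dilution bookkeeping and are
exempt from elemental balancing by definition; their mass is accounted
on the biomass-dilution row instead.

## Deliberate design choices

**Pathway-equivalent turnover numbers.** Lumped steps (the methyl
branch, glycolysis halves, anabolic lumps) stand for several enzymes
each, so they carry keff values well below the 25/s single-enzyme
default (0.5–8/s). This is what places the proteome-limited knee of the
growth curve inside the 0–30 mmol/gDW/h uptake window at desk scale.
The acetate route yields more ATP per CO (0.50 vs 0.42), while the
ethanol route needs less of the expensive methyl-branch proteome per
CO; carbon limitation therefore selects acetate and proteome limitation
ethanol — the overflow switch.

**Electron-neutral anabolism.** In a strict steady-state LP every
biomass component must be exactly redox-balanced against the substrate,
or growth strands reducing power whenever the WLP sink is unavailable
(converting sugar-derived acetate to ethanol is redox-neutral overall
and can never absorb a surplus). Every anabolic lump therefore consumes
exactly one NAD(P)H pair per pyruvate and two per acetyl-CoA it draws;
nucleotide lumps use fractional amino-acid skeletons solved exactly
from a 6x6 element/charge system (`toy_nmp_lump()`). Rnf is reversible
(proton-motive-force-driven ferredoxin reduction), so mixed
NADH/ferredoxin requirements interconvert at an energetic cost. Two
consequences reproduce the target phenomenology: on fructose the
surplus reducing power of catabolism drives WLP CO$_2$ recapture
(mixotrophy), and with nickel removed only the redox-neutral ethanol
route remains — growth persists with zero acetate secretion.

**Protein is the biomass filler.** RNA can be cheaper per gram than
protein in synthesis terms, but cells regulate composition rather than
cost-optimize it. Stable RNA is therefore sized exactly by machinery
need (no overproduction route into biomass mass), surplus RNA decays
back to NMPs without biomass credit, and the flexible share of the
biomass-dilution row is filled by protein. The M-side biomass reaction
is constructed from the same composition (protein-dominant fill, same
demands, same GAM), which is what makes the zero-expression-cost limit
of the ME model coincide with plain FBA to within a percent — an
identity, not a fit.

**Closed proton/hydrogen economy.** Protons cross the membrane only
through Rnf, ATP synthase and the acetate symporter; H$_2$ secretion is
closed (the exchange admits only uptake). A free proton or H$_2$ valve
would let the LP either fabricate ATP from medium protons or bypass the
ethanol/WLP electron-disposal trade-offs the analyses probe.

**Maintenance and the closed-exchange convention.** The toy carries
NGAM, so a network with every exchange closed is genuinely infeasible
(maintenance cannot be met) and `solve_fba()` reports that;
maintenance-free networks return an optimal zero. Both behaviors are
tested.

**Minimum resolvable growth.** Usage couplings scale as
$\mu/(3600\,k_\mathrm{eff})$; below $\mu \approx 10^{-3}\,h^{-1}$ they
fall under the LP feasibility tolerance ($10^{-9}$) and any cofactor or
enzyme requirement becomes numerically invisible — bisection would
report artifact growth where the true supremum is zero (observed for
CO growth with nickel shut off; an independent solver shows the same
tolerance behavior). `mu_min` therefore defaults to
$10^{-3}\,h^{-1}$ and infeasibility there is reported as `no_growth`
with $\mu^\ast = 0$.

**Terminators are metadata.** Rho-dependent versus rho-independent
termination carries no coefficients; the flag is retained for schema
fidelity only. Selenocysteine is not modeled.

# The LP engine

No linear-programming backend ships with the supported R stack, so the
package carries a dense revised simplex (`src/simplex.cpp`): two-phase,
LU-factorized basis with an eta file refactorized every few dozen
pivots, column/row equilibration, Harris-style ratio test, pivot-size
rejection of entering columns that would breed near-singular bases,
Bland fallback on stalling, a dual-simplex repair pass restoring primal
feasibility after phase 2, and a final exact re-solve of the basic
system so steady-state residuals come out near machine precision. A
bound-propagation presolve removes the large blocks of structurally
dead columns that closed exchanges cascade through cofactor-loading
rows — most of the degeneracy these instances otherwise exhibit. The
solver is validated against a vertex-enumeration oracle on random small
networks; ME instances were additionally cross-checked against an
independent external solver during development. The interface is
pluggable by construction (everything goes through `lp_solve()`), so a
quasi-exact backend could replace it for full-scale models.

Numerical conventions: feasibility and optimality tolerances $10^{-9}$;
all coefficients in per-hour units; a returned point whose constraint
violation exceeds $10^{-4}$ is never reported as an optimum (the
extraction path backs off $\mu$ by a few tolerance steps instead).

# Statistics

`expression_growth_corr()` correlates per-gene transcription flux with
growth across sweep points and attaches a permutation p-value: each
gene's expression vector is shuffled (1000 times by default) and
Pearson r recomputed, $p = (1 + \#\{|r_\pi| \ge |r|\})/(1 + n_\pi)$;
with `exact = TRUE` all $n!$ permutations are enumerated instead. With
1000 shuffles the smallest attainable p is $1/1001$, which is larger
than any Bonferroni threshold $0.05/n$ once more than about 50 genes
are tested — so the `significant` call uses the parametric two-sided
Pearson test at $\alpha = 0.05/(\text{genes with defined } r)$, while
the permutation p is reported alongside and is what the calibration
check exercises at nominal $\alpha$. Genes with constant expression
have undefined r and are excluded from the multiple-testing count.
Category aggregation (`aggregate_by_category()`) sums mass-weighted
transcription fluxes (flux times molecular weight) and optionally
max- or sum-normalizes; per-gene correlations use raw fluxes.

# What the synthetic data does and does not establish

`synth_expression_dataset()` emulates an expression readout: observed
values are true transcription fluxes under multiplicative lognormal
noise, plus planted null genes drawn independently of growth, with
ground-truth labels. A green recovery test establishes that the
pipeline detects growth-linked expression at the stated noise and is
calibrated under the null. It does not establish anything about
real-read count distributions (overdispersion, library-size effects,
mapping artifacts), about regulation (the toy's expression is purely
demand-driven), or about the numerical values a full genome-scale
reconstruction would produce — those require the reconstruction
content itself, which is outside desk scale. Likewise the toy
reproduces full-scale acetogen ME phenomenology qualitatively (overflow order,
glycerol recycling versus secretion, nickel essentiality and the
unequal CODH4/CODH_ACS activity decline) but not its printed
full-model numbers (e.g. the acetate:ethanol ratio of 1.4).

# Known limitations

* The dense simplex targets hundreds of rows/columns; full-scale ME
  models need a sparse, quasi-exact backend.
* Machinery efficiencies are constant in $\mu$; some ME formulations
  couple them hyperbolically to growth. The constant-rate choice is
  flagged here and isolated in `coupling_params()`.
* Cofactor mass is not counted in the biomass-dilution row (it is
  orders of magnitude below macromolecule mass at these compositions).
* The membrane capacity constraint (`membrane_gamma`, default 2 g
  membrane protein per g lipid, toggleable) bounds membrane-protein
  amount against lipid synthesis; its form is a modeling convention
  since only the existence of a bilayer constraint is documented for
  the reference model.
* One multi-gene stable transcription unit covers both rRNA and tRNA;
  surplus of either decays to NMPs. Real stable-RNA operon structure is
  richer.
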