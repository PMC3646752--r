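---
title: "Modeling the yeast protein secretory machinery with secflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the yeast protein secretory machinery with secflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secflux)
```

## The model

The secretory machinery of *Saccharomyces cerevisiae* — the ER, the Golgi
and the vesicular routes between them and the cell surface, vacuole and
wall — processes every secreted and most membrane proteins: translocation
into the ER, N- and O-linked glycosylation, disulfide bond formation,
GPI-anchor attachment, quality control and degradation, and coat-mediated
transport. `secflux` represents this machinery at genome scale in three
layers:

1. **The PSIM** (Protein Specific Information Matrix): one row per
   protein, seven features — signal peptide (presence), N-glycosylation
   sites (count), O-glycosylation sites (count), disulfide bonds (count),
   GPI anchoring (presence), transmembrane domains (count), final
   localization (ER, Golgi, membrane, vacuole, extracellular, unknown).
   Counts are kept quantitative; presence/absence booleanization happens
   only at classification time.

2. **The secretory class catalog**: every feasible combination of
   booleanized features. A protein's class determines its itinerary
   through the machinery. Under the default feasibility rules the catalog
   holds 186 classes.

3. **The machinery network**: 163 molecular components (162 proteins plus
   the SCR1 RNA of the signal recognition particle) organized into 16
   functional subsystems (S1 Translocation through S16 ALP pathway)
   across 8 compartments, connected by 137 reactions in four categories —
   56 protein-generic *template* reactions, 26 *complex formation*
   reactions, 30 *biosynthesis* reactions (dolichol-linked oligosaccharide
   and GPI-anchor assembly) and 25 *exchange* reactions that connect the
   machinery to the rest of metabolism across a virtual system boundary.

On top of these, three steady-state calculators:

* **Processing rates.** At steady state with specific growth rate
  $\mu$ (h$^{-1}$), each client protein with abundance $P_p$
  (molecules·cell$^{-1}$) must be processed at
  $v_p = \mu P_p$ (molecules·cell$^{-1}$·h$^{-1}$). Each machinery
  reaction $j$ then runs at $v_j = \sum_p S_{j,p}\, v_p$, where
  $S_{j,p} \in \{0,1\}$ indicates membership of reaction $j$ in protein
  $p$'s reaction list, and each metabolite $x$ is consumed at
  $r_x = \sum_j C_{x,j}\, v_j$ with the instantiated (feature-scaled)
  stoichiometric coefficients $C_{x,j}$.

* **Synthesis cost.** A protein's biosynthetic price is
  $\sum_{aa} n_{aa} c_{aa} + 4\,(L-1)$ ATP equivalents (plus the NADPH
  side of the residue costs): the residue biosynthesis costs plus 4 ATP
  equivalents per peptide bond (2 ATP for tRNA charging, 1 GTP for
  ribosome binding, 1 GTP for elongation).

* **Specific activity.** Each component's SA is its catalytic throughput
  per molecule: $SA_i = \sum_j v_j\, \sigma_{i,j} / C_i$, with
  $\sigma_{i,j}$ the catalytic stoichiometry (default 1 per
  participation) and $C_i$ the component's own abundance. Components
  acting through a complex inherit the complex's catalyzed flux; a
  reaction serving two subsystems is counted once per component.

## The class catalog and its feasibility rules

The combinatorial space of the seven features is pruned by mechanistic
constraints, encoded in `constraintConfig()` as enumeration blocks rather
than in code:

* **SP+ category** (N-terminal signal peptide): the three glycosylation /
  disulfide slots are free ($2^3$), crossed with three membrane states —
  GPI-anchored (admissible destinations: membrane, extracellular,
  vacuole), non-GPI membrane-spanning (5 destinations) and non-GPI
  soluble (5 destinations): $8 \times (3 + 5 + 5) = 104$ classes.
* **SP− category** (no signal peptide): entry into the ER requires a
  signal anchor, so the TM slot is forced present; GPI is free:
  $8 \times 2 \times 5 = 80$ classes.
* Two **catch-all** classes, one per category, absorb clients with
  unknown localization.

Total: 186. The GPI-admissible localization set is the least certain of
these defaults and is deliberately exposed as the first argument of
`constraintConfig()`.

Two classification conventions are worth spelling out. First, an SP+
record that is both GPI-anchored and TM-annotated booleanizes its TM slot
to absent — the GPI membrane state dominates, reflecting the catalog's
factorization of SP+ membrane states; SP− records keep their TM slot,
since the TM segment is their ER-entry signal. Second, an SP+ GPI record
whose annotated destination falls outside the admissible set (e.g. ER)
has no regular class; it is assigned to the category catch-all with a
diagnostic note rather than erroring, since annotation conflicts of this
kind occur in real feature tables.

```{r}
catalog <- enumerateClasses()
catalog
```

## The packaged machinery network

The model document (`inst/extdata/yeast_machinery_model.yaml`) is a
curated reconstruction sized to the published census of the yeast
machinery — 163 components, 16 subsystems, 8 compartments, 137 reactions
split 56/26/30/25 by category. Reaction-level composition is best-effort
from the mechanistic literature (SRP targeting, Sec61 translocation, OST
glycan transfer, Ero1–PDI oxidative folding, HRD/DOA10 ERAD, COPII/COPI
coats, mannan polymerases, exocyst, AP-3), with a note field per reaction;
component membership in subsystems drives the bipartite network export.

```{r}
m <- yeastModel()
str(validateModel(m), max.level = 1)
```

Template reactions carry an *applicability* predicate over the client's
features (e.g. `n > 0 && loc != 'ER'` for Golgi outer-chain elongation)
and a *scale* expression that multiplies the per-event stoichiometry
(e.g. `n` for per-site reactions, `4*n + o + 4*g` for dolichol-phosphate-
mannose synthesis, which feeds four lumenal core mannoses per N-glycan,
one mannose per O-site and four per GPI anchor). A plain feature name is
the common case; the expression form exists because some precursors pool
demand from several features.

### Numerical and routing conventions

* Stoichiometry sign: positive = consumed per catalytic event; negative =
  produced. The headline demand `consumption` sums positive contributions
  (the boundary draw); `net` additionally subtracts production, so
  pathway intermediates (LLO, Dol-P-Man, Dol-P-Glc, GPI-anchor) net to
  zero — a built-in mass-balance check on the instantiation.
* Core N-glycan stoichiometry is canonical Glc₃Man₉GlcNAc₂: per site,
  2 UDP-GlcNAc + 5 GDP-mannose (cytosolic steps) + 4 dolichol-P-mannose
  (lumenal steps) + 3 dolichol-P-glucose, with one de novo dolichol
  carrier (from farnesyl-PP) per glycan. Golgi processing defaults to one
  outer-chain initiation, one elongation and one terminal mannosylation
  event per N-site and one elongation per O-site. All of these live in
  the model document, not in code.
* Routing: ER residents receive no transport steps (their itinerary is
  translocation, modification and folding only); Golgi residents travel
  COPII and are retained by COPI retrieval; membrane proteins exit via
  low-density secretory vesicles, extracellular and cell-wall proteins
  via high-density vesicles; vacuolar proteins take the endosomal CPY
  route by default, with a per-protein override list
  (`reactionOptions(alp_proteins=)`) for the direct AP-3/ALP route —
  the literature gives no general per-protein rule. Clients with unknown
  localization are routed as extracellular, the most common fate of an
  unannotated signal-peptide protein; their class, however, is the
  catch-all.
* ERAD: the misfolded fraction `f_misfold` defaults to 0 — the machinery
  description gives no value — and, when positive, scales a
  three-to-four-step degradation branch (ubiquitination consuming
  ubiquitin and ATP, retrotranslocation by the Cdc48 machine) chosen by a
  feature heuristic: membrane-spanning substrates → ERADM, lumenal
  glycosylated → ERADL, otherwise ERADC.
* Rates versus stoichiometry: reaction membership $S_{j,p}$ is 0/1, so a
  reaction's rate $v_j$ counts one event per client molecule even when
  its metabolite draw is scaled per site. Per-site multiplicity therefore
  enters the demand $r_x$ (through $C_{x,j}$) but not the specific
  activity, which follows the membership definition literally. Users who
  prefer site-resolved SA can pre-scale component abundances.
* $\mu$ has no default: it is condition-specific. 0.35 h$^{-1}$
  (exponential growth on glucose) is a reasonable illustration value.
  Clients missing from the abundance table default to 1 molecule per
  cell, keeping them in the network with negligible weight.
* The amino-acid cost table ships as an editable TSV of textbook-derived
  ATP/NADPH equivalents; only the arithmetic of the cost equation is
  asserted by tests, never the table's values.

## The synthetic proteome generator

Real inputs (UniProt-derived feature tables, steady-state abundance
surveys) are not redistributable at desk scale, so every stage is
exercised on synthetic proteomes with controlled structure
(`generateProteome()`): Bernoulli signal-peptide and GPI priors
(GPI conditional on the signal peptide, since anchor attachment requires
ER entry), Poisson site/bond/domain counts, a categorical localization
distribution, log-normal abundances (log₁₀ mean 2, sd 1 — spanning the
1–10⁵ molecules·cell⁻¹ range between rare chaperone cofactors and the
most abundant cell-wall proteins; a package choice, not a literature
value) and uniform-random sequences (the cost equation needs only
residue counts, so no compositional realism is attempted). Each proteome
carries a truth ledger — intended category, class signature and an
independently recounted expected step count per protein — against which
classification and instantiation are tested for exact agreement.

What passing these tests shows: the combinatorics, routing logic and
linear algebra of the calculators are correct. What they do not show:
agreement with any particular organism's measured demands — synthetic
feature priors are not UniProt's annotation distribution, and synthetic
abundances are not a proteomics survey. Absolute demand levels, the
published specific-activity table and the published log₁₀(SA)
distribution fit all depend on external datasets and curation choices
and are explicitly out of reach at desk scale; the package reproduces
the computation, not those numbers.

A fixed five-protein micro-proteome (`workedExample()`) covers the five
archetypal routes — GPI cell-wall protein, SP− multi-pass proton pump,
vacuolar protease, secreted pheromone, ER chaperone — at unit abundance
and $\mu = 1$, so every per-event coefficient is legible in the demand
report. Its expected demand table was computed by an independent
implementation that reads the model document directly, and is frozen
under `extdata/` for the test suite.

```{r}
we <- workedExample()
lists <- generateAll(we$psim, enumerateClasses(), m)
dem <- metaboliteDemand(lists, m, we$context, psim = we$psim)
head(demandTotals(dem), 8)
```

## Problem sizes and determinism

The test suite runs on synthetic proteomes of 40–1000 proteins and
checks the vectorized calculators against naive loop oracles at 1e-9
relative tolerance on proteomes up to 500 proteins; class-catalog
enumeration and the packaged-model census are exact. All randomness is
seeded; catalog enumeration, reaction instantiation and the CLI pipeline
are deterministic (two runs with identical manifests are byte-identical).

## Known limitations

* Reaction-level fidelity of the packaged network to the primary
  literature is best-effort; the census (163/16/8/137, 56/26/30/25) is
  exact, but individual catalyst assignments are approximations in
  places (noted per reaction in the model document).
* The network is a demand-accounting scaffold: no flux-balance
  optimization, no kinetics, no queueing, no capacity constraints.
* Unconventional (leaderless) secretion is out of scope; SP− clients are
  modeled only through the signal-anchor route.
* Outer-chain length, O-glycan elongation extent and ERAD stoichiometry
  are configurable defaults, not measurements.
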