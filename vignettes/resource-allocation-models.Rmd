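---
title: "Resource-allocation models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-allocation models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model underlying `ramtool`, the assumptions it
makes, the tunable parameters, and the design decisions taken where the
formalism leaves room. It is the companion to the function reference; the
README shows a worked session.

## The model

A resource-allocation model partitions the `n` species of a metabolic
network into four classes: extracellular species `Y` (amounts `y(t)`,
mmol), internal metabolites `X` (`x(t)`), storage compounds `C` (`c(t)`),
and macromolecules `P` (`p(t)`) — the enzymes, the ribosome, and
noncatalytic *quota* compounds such as cell wall or lumped noncatalytic
protein. Reactions split correspondingly into exchange reactions `R_y`,
internal metabolic reactions `R_x`, storage interconversions `R_c`, and
macromolecule synthesis reactions `R_p`. In `ramtool` the reaction class
is derived deterministically from the species types a reaction touches
(any extracellular species makes it `R_y`; otherwise producing a
macromolecule makes it `R_p`; otherwise touching storage makes it `R_c`;
else `R_x`), and a reaction mixing extracellular species with
macromolecules or storage is rejected as unclassifiable.

Two biomass readouts are used throughout. The *objective biomass*
`B_o = b_P' p` weighs macromolecules by their objective weights `b_i`
(g/mmol, typically equal to the molecular weights `w_i`, possibly zero
for, e.g., secreted enzymes). The *total biomass* `B_t = B_o + w_C' c`
additionally counts storage mass; storage scales the biomass-proportional
constraints but, by default, earns no objective credit (including it can
produce unrealistic growth modes).

**deFBA** maximizes `∫ B_o(t) dt` over fluxes subject to: the species
dynamics `d/dt [y;x;c;p] = S v`; the quasi-steady-state assumption
`d/dt x = 0` (metabolite pools are negligible relative to turnover);
optional flux box bounds; the enzyme capacity constraint
`H_C v ≤ H_E p`, where each row collects `Σ v_j / kcat_j` over the
reactions catalyzed by one enzyme and `H_E` selects that enzyme's amount
(exactly one unit entry per row); the biomass composition constraint
`H_B [c;p] ≤ 0`, one row per quota species `s` encoding
`w_s p_s ≥ φ_s B_t`; and maintenance floors `v_m ≥ ψ_m B_t` for
spontaneous ATP-hydrolysis reactions flagged by `ψ_m > 0`. Because
amounts (not concentrations) are modeled, every constraint is linear.

A note on the maintenance inequality: written in matrix form it formally
ranges over all fluxes, but since `ψ_m = 0` everywhere else only the rows
of maintenance reactions are enforced; other fluxes are bounded below
only by their box bounds. Maintenance reactions are kept inside `R_x` and
identified solely by `ψ_m > 0`.

**RBA** fixes a growth rate `μ` and asks whether balanced exponential
growth is feasible: `S_X v = 0`, `S_P v = μ p`, `S_C v = μ c`, capacity,
quota and maintenance constraints, and the normalization `B_t = 1` g.
`solve_rba_initial()` locates the largest feasible `μ` by bisection
(default bracket `[0, max kcat]` — no enzyme-limited network can
replicate its catalysts faster than its fastest catalyst — and absolute
tolerance `1e-6` h⁻¹), then rescales the feasibility point linearly to
any requested biomass. Nutrients reported absent (`y0 = 0`, non-boundary)
have their consuming flux directions blocked.

## Discretization and numerics

The dynamic problem is discretized by collocation on a uniform grid with
`n_steps` intervals: amounts live on the nodes, fluxes are piecewise
constant per interval, so the dynamics integrate exactly to
`y_k − y_{k−1} = Δt · S v_k`. Under the default `implicit_euler` scheme
the capacity, quota, and maintenance constraints are enforced at the
right node of each interval and the objective uses right-endpoint
quadrature; the `trapezoid` scheme enforces them at both interval ends
and uses trapezoidal quadrature. Implicit Euler keeps the LP small and
biases the objective slightly upward (for the analytic self-replicator
the per-step growth factor is `1/(1 − kcat Δt)` instead of
`exp(kcat Δt)`, a first-order bias `≈ μ²Δt/2` in the growth rate);
trapezoid converges from below. Nonnegativity is enforced at the nodes
only — a discretization property, not a modeling statement about the
continuous trajectory between nodes.

Reversible fluxes are split internally into nonnegative forward and
backward parts `v = v⁺ − v⁻`, and a capacity row reads
`v⁺/kcat⁺ + v⁻/kcat⁻ ≤ p_i`. This is the linearization that bounds both
directions of a reversible catalyzed reaction with direction-specific
turnover numbers; box bounds are imposed on the net flux.

The LPs are solved by HiGHS through SciPy's `linprog` in a small Python
helper shipped with the package (JSON in, JSON out), with primal/dual
feasibility tolerances of `1e-10`; returned trajectories are re-checked
in R against every constraint family, and the tests require residuals
below `1e-8`. Infeasible or unbounded problems surface through the
`status` field of the trajectory — amounts are never clamped. Ties among
degenerate optima are backend-dependent, so tests assert objective values
and residuals, never flux uniqueness.

Problem sizes used in the test and acceptance runs — chosen so the whole
collocation LP stays in the hundreds-of-variables range where behavior is
transparent — are 16–128 steps for the analytic self-replicator and 20
steps over 1 h for the toy model.

## The builder protocol

`protein_synthesis_reaction()` turns amino-acid sequences into synthesis
reactions: residue counts per subunit are multiplied by the subunit's
copy number (a homotrimer costs three times its gene's residues) and
summed across the genes of a complex. Translation energy is accounted
either in `detailed` mode — per residue, 1 ATP → AMP + PPi for charging
and 2 GTP → 2 GDP + 2 Pi for elongation — or in `lumped` mode for models
that do not track GTP, charging `atp_per_aa` ATP → ADP + Pi per residue.
The lumped default of 4 counts the three detailed hydrolysis equivalents
plus one for amino-acid activation; it is a documented, overridable
convention since no canonical constant exists. Residue-to-metabolite
naming is a configurable map (`default_residue_map()` targets
three-letter ids) so the builder can address any reconstruction's
namespace. FASTA input is standard multi-record FASTA via `Biostrings`;
`*` stop characters are stripped, ambiguity codes (B/Z/X/U) are rejected
by default with an opt-in mapping to the nearest standard residue, and
rRNA components of the ribosome can be passed as extra subunits with a
custom residue map onto nucleotide precursors.

The ribosome is an enzyme whose rate for making one protein is the
elongation rate over the protein length, `kcat = a / l`, converted to
1/h (`ribosome_kcat(15, 100)` = 540 h⁻¹). Isoenzymes are handled by
copying the catalyzed reaction once per isoenzyme
(`split_isoenzyme_reactions()`), which preserves the reachable flux cone
while keeping every reaction bound by exactly one gene product — the form
the RAM dialect requires. Enzymes acting in several compartments become
distinct species with ids `Main_id_[compartment]`
(transporters: `Main_id_[c1]_[c2]`).

Quota compounds lump groups of biomass-reaction substrates. From the
biomass coefficients `S_i` (mmol/g) and monomer weights `w_i`,
`build_quota_reaction()` computes the mass fraction `φ = Σ S_i w_i`,
divides all component, byproduct, and polymerization-energy coefficients
by `φ`, and emits a reaction producing one quota unit of exactly 1 g
(the normalization is checked to `1e-9` in the tests). The noncatalytic
protein quota is special: its fraction is reduced by the explicitly
modeled proteome share, `φ_quota = φ_protein (1 − f_e)`
(`adjust_protein_quota()`), and its synthesis is ribosome-catalyzed with
a rate from the same elongation formula using the summed amino-acid
coefficient as the "length" — which makes the unit 1/(mmol·h) rather
than 1/h; the value is tagged accordingly. Whether the weights entering
`φ_protein` are residue masses or free amino-acid masses is not fixed by
the formalism; the builder takes weights as given input. The shipped
`yeast_protein_quota_table()` is a *synthetic reconstruction* of the
standard yeast charged-tRNA composition with free amino-acid weights; it
yields a protein fraction of ≈0.467, in line with protein being roughly
half of yeast dry weight.

Turnover rates from databases are filtered to wild-type observations and
aggregated; the enzyme-wise **median** over organisms is the default
(it approximates in vivo rates better than the mean or the
closest-sequence organism), with `assign_kcat()` providing the fallback
chain same-organism → other-organism median → user default, each use
logged. Automated database retrieval and sequence-similarity transfer
are out of scope.

## Validation utilities

`fit_growth_rate_from_od()` estimates the culture growth rate as the
ordinary-least-squares slope of `ln OD` versus time over all supplied
points; windowing to the exponential phase is deliberately left to the
caller. The model growth rate is the log-slope of total biomass,
per interval (`instantaneous_growth_rate()`) or over the whole horizon;
under saturating nutrients it is constant up to the collocation bias and
provides an upper bound on the measured rate. When the model overshoots,
`tune_maintenance()` bisects the maintenance coefficient `ψ` — the model
growth rate decreases monotonically in `ψ` — until the measured rate is
matched; if the measured rate exceeds the model optimum at `ψ = 0` the
error message points at the turnover-rate parameterization instead.

## The toy fixture and synthetic generators

`toy_model()` builds the 14-species/14-reaction self-replicating toy
cell programmatically, with the published structure: stoichiometries,
turnover rates (including the direction-specific storage rates 25/30 and
the spontaneous maintenance drain of 50 AA + 60 ATP), the nonlimiting
boundary oxygen, and the initial ribosome (0.03364 mmol) and structural
(0.7499 mmol) amounts. Quantities the published structure leaves open are
exposed as arguments with fixture defaults: molecular weights equal to
the synthesis chain length / 1000 for enzymes, ribosome, and storage;
`ψ = 0.01` mmol/(g·h); `bp_S = 0.3`; 0.01 mmol of each enzyme and
10 mmol N2 initially. The structural component's weight is the one
deliberate deviation from the chain-length rule: at 1.5 g/mmol the quota
compound would yield 15 g of objective biomass per ribosome-hour versus
1 g for every enzyme, and the optimal strategy would degenerate into
quota accumulation with a non-constant growth rate. Its default of
0.08 g/mmol sits below that parity point, so structural biomass is
produced to satisfy the quota, and the deFBA optimum under saturating
nutrients is balanced exponential growth consistent with the RBA rate.
These are fixture choices, not published values.

The synthetic generators make every module testable offline:
`random_ram_model()` draws small structurally valid models for the
SBML round-trip and matrix-property tests, and
`random_builder_fixture()` emits FASTA records, gene–reaction maps, and
subunit stoichiometries for the builder. They emulate the *structure* of
real inputs — valid alphabets, consistent references, plausible
magnitudes — not their biology: no genome-scale coupling, no realistic
kcat distributions, no compartmentalization depth. Tests passing on them
establish the correctness of the machinery, not predictive accuracy on
any real organism, which always requires the validation step above
against measured growth data.

## The RAM SBML dialect

Models serialize as SBML L3V1 with the fbc v2 package and `ram:*`
annotations (namespace `https://www.fairdomhub.org/sops/304`). Every
species carries `ram:speciesType` (extracellular / metabolite / storage /
enzyme / quota); storage and macromolecule species carry
`ram:molecularWeight`, `ram:objectiveWeight`, and `ram:biomassPercentage`;
every reaction carries `ram:kcatForward`, `ram:kcatBackward`, and
`ram:maintenanceScaling`. Numeric attributes are written as references
into the parameter list (`weight_<species>`, `bp_<species>`,
`kcat_fwd_<reaction>`, `psi_<reaction>`, a shared `zero`); the reader
accepts parameter ids and literal numbers interchangeably. Nonlimiting
extracellular species get `boundaryCondition="true"` (and
`constant="true"` unless driven externally); everything else is
`false`/`false`. Amounts may be given as `initialAmount` or as
`initialConcentration` times the compartment size. Gene products carry
the complex recipe verbatim in `fbc:label` (never parsed for semantics),
reactions reference at most one gene product (complexes are pre-resolved,
isoenzymes pre-split; an association tree would be a validation error),
spontaneous reactions — maintenance included — have no association at
all, and EC numbers travel as MIRIAM `isVersionOf` annotations. The
`fast` attribute is emitted as `"false"` for L3V1 compatibility and will
be dropped when targeting L3V2. `ram:biomassPercentage` is always written
(as `zero` where it does not apply) but tolerated as absent on read,
defaulting to 0. Unknown foreign annotations are preserved opaquely
through round trips. `validate_ram_document()` checks these rules
structurally and reports located, severity-tagged findings — including a
warning when one macromolecule id is reused across compartments, the
classic pitfall the id convention exists to prevent. Full SBML schema
validation beyond the dialect rules is out of scope.

Numbers are printed with 17 significant digits, so write/read round
trips reproduce IEEE doubles exactly; the round-trip tests compare at
tolerance zero.

## Known limitations

No kinetic rate laws, regulation, or concentration/volume effects;
growth optimality is assumed, which is questionable under starvation;
tRNA charging, cofactors, and prosthetic groups are not modeled in
enzyme synthesis (they can be approximated as quota compounds); cyclic
steady-state and stochastic/robust variants of the dynamic problem are
not implemented. Genome-scale dynamic problems are limited by LP size —
the dynamic formalism is practical up to a few hundred metabolic
reactions, while the balanced-growth problem scales further.
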