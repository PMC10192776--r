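---
title: "Methods: conservation, phylogenetics and bioenergetics of oxalotrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation, phylogenetics and bioenergetics of oxalotrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oxalotrace` supports surveys of the bacterial oxalate-degradation genes
*oxc* (oxalyl-CoA decarboxylase), *frc* (formyl-CoA transferase), *oxdC*
(oxalate decarboxylase) and *oxlT* (oxalate:formate antiporter). Such a
survey asks three questions: do candidate sequences recovered from public
databases retain the functionally critical residues of the characterized
enzymes; do the genes' phylogenies group by taxonomy or by source
environment; and is the catabolism energetically plausible in the marine
settings where new candidate sequences keep appearing. This vignette
documents the models and procedures behind each stage, the tunable
parameters, the synthetic-data generator used for testing, and the
numerical choices that an analyst extending the package should know about.

## Hit curation

BLAST tabular hits (outfmt 6/7) are retained when `e_value < e_max`
(default `1e-50`) and fractional `percent_identity < pid_max` (default
`0.87`); both bounds are strict, so boundary values are removed. The upper
identity bound excludes trivial recoveries of the query itself and its
near-duplicates; the E-value bound enforces homology. Identity is stored
internally as a fraction; files on the 0--100 scale are declared via
`pid_scale = "percent"` — the dialect is never guessed from the data. One
best hit (lowest E-value) is kept per subject by default, because each
retained protein becomes one tree tip.

Where thresholds alone leave more than `target_max_records` (default 200)
hits, the survey's "fewer than 200 sequences" working-set target is
enforced by a deterministic rule of this package's design: rank by
ascending E-value, break ties lexicographically by subject id, truncate,
and log the truncation. A deterministic rule was preferred over manual
re-querying because it makes the curated set a pure function of the input
table and the policy. Every removed record is attributed to exactly one
rule, the first it fails in the fixed order E-value, identity, dedupe,
cap; the attribution counts form the `FilterReport`.

## Key-residue conservation

Key residues are positions shown by mutagenesis (as catalogued in
UniProtKB) to be functionally critical. They are specified in 1-based
ungapped coordinates of a reference sequence and mapped through the
gapped alignment to 0-based columns; both numbering conventions are
stated in every report to avoid off-by-one drift. The package ships the
residue sets that are enumerable for *oxc* (E-56, Y-120, E-121, Y-483,
S-553, R-555), *oxdC* (R-270, E-333, Y-340) and *frc* (Q-17, W-48, D-169,
G-259, G-260); the twelve *oxlT* residues are not enumerated in the
literature record the package draws on and must be user-supplied.

At a scored column each record is in one of three states: it carries a
residue; it has an internal gap; or it is *terminated* — the gap run
containing the column extends to an alignment edge. Terminal runs are the
signature of truncated metagenome-assembled-genome (MAG) fragments, and
both trailing and leading runs count, since fragments truncate at either
end. Termination is reported separately from substitution because an
absent residue says nothing about functional divergence.

Two identity denominators are reported, because published usage is
ambiguous between them: `pid_all` (matches over all records) and
`pid_occupied` (matches over records with any residue at the column),
linked by the exact identity
`pid_all = pid_occupied * occupancy`, which the test suite asserts on
every report. `X` residues count toward occupancy but never match;
comparison is case-insensitive and `.` is read as a gap. Reports can be
restricted by record class (isolate, MAG, transcript, fungal outgroup);
the position mapping always uses the full alignment, so the reference
sequence need not belong to the scored subset.

Sequence-logo matrices give gap-excluded per-column residue frequencies
and Shannon information content `IC = log2(20) - H` in bits, ranging from
0 (uniform) to `log2(20) ~ 4.32` (invariant column). The small-sample
(Miller--Madow) correction is available but off by default, matching
common logo-rendering practice.

## Phylogenetics

Distances are uncorrected p-distances with pairwise deletion: the
proportion of mismatches over columns where both records carry a
character, with `X` matching nothing. The distance model is deliberately
the simplest defensible choice and is isolated behind `p_distance()` so a
corrected model can be substituted; a pair with no comparable columns is
an error rather than a guess.

Neighbor joining is implemented in the package (Saitou--Nei agglomeration
under the standard Q-criterion) rather than delegated, so that its
tie-breaking is pinned: ties in Q resolve to the lowest (i, j) index pair,
making runs exactly reproducible; negative branch lengths are clamped to
zero with a message. On additive matrices the algorithm is exact, which
the tests verify by round-tripping random trees through their path-length
matrices (4--12 taxa, path lengths recovered to 1e-9) and by topology
comparison against ape's independent C implementation. Maximum-likelihood
inference is out of scope; externally built ML trees are consumed via
Newick files, with internal node labels parsed as bootstrap supports.

Branch support uses column bootstrapping: alignment columns are resampled
with replacement, a replicate NJ tree is built per resample, and each
internal edge of the reference tree is scored by the percentage of
replicates containing the same bipartition (500 replicates by default,
matching common practice for published trees; the seed is mandatory).

Clade--metadata concordance quantifies "grouping by taxonomy" or
"grouping by source environment" claims: every internal node with support
at or above a threshold (default 50, mirroring the usual display cutoff)
is scored for label purity — the largest fraction of its tips sharing one
metadata label — and the summary counts *maximal* pure clades per label,
i.e. pure clades not nested inside a larger pure clade of the same label.
Labels are compared case-insensitively after trimming; missing values
become `"unknown"`. Note that the arbitrary root of an unrooted tree is
never evaluated (it has no support), so a group that happens to contain
the root appears as the complement of the other group's clade rather
than as a clade of its own.

iTOL colorstrip datasets are exported with a deterministic label-to-color
assignment (sorted labels onto a fixed qualitative palette), so
re-exports are byte-identical.

## Aqueous bioenergetics

The engine computes apparent standard molal Gibbs energies of aqueous
species with the revised Helgeson--Kirkham--Flowers (HKF) equation of
state and combines them into reaction energies. The two evaluable survey
reactions are oxalotrophy at circumneutral pH,

    C2O4^2- + H2O -> HCOO- + HCO3-

and the low-energy marine comparison metabolism, anaerobic methane
oxidation coupled to sulfate reduction (AOM-SR),

    SO4^2- + CH4(aq) -> HS- + HCO3- + H2O.

The classical schematic that writes oxalate degrading to a generic "CHO"
organic plus bicarbonate is shipped only as documentation
(`reaction_ocp_schematic()`): a generic CHO molecule is not a defined
aqueous species, so `validate_reaction()` rejects it explicitly. All
evaluable reactions must balance element-by-element and in charge in
exact integer arithmetic before evaluation.

For each species, `G(T, P)` is the reference-state formation value at
25 °C and 1 bar plus entropy, heat-capacity (`c1`, `c2` with
`theta = 228 K`), volumetric (`a1..a4` with `psi = 2600 bar`) and Born
solvation terms; the Born term uses a constant `omega` with the
conventional `Y(Tr, Pr)` correction. The high-temperature "g-function"
correction to `omega` is omitted — it is negligible below roughly 150 °C —
and the engine range is capped accordingly at 0--100 °C and 1--500 bar.
The dielectric constant of water is the Bradley--Pitzer (1979)
formulation (78.38 at 25 °C, 1 bar), with the Born functions `Q`, `Y`,
`X` obtained from it by central differences. Liquid water itself is not
an HKF species: its Gibbs energy integrates a calorimetric heat-capacity
polynomial and a Kell (1975) density surface with a fitted isothermal
compressibility, from the same reference-state value used by the
SUPCRT-lineage compilations. Conditions below the liquid--vapor
saturation pressure are evaluated at saturation on the liquid branch
(with a message), so a nominal "100 °C at 1.01 bar" grid point is well
defined. Note one physical subtlety the test suite respects: liquid water
is densest near 4 °C, so density is only monotonically decreasing in
temperature above that maximum.

Species parameters are embedded as a citation-tagged CSV
(`inst/extdata/hkf_species.csv`) in the conventional scaled calorie
units, with reference-state values in kJ/mol and J/(mol K). The rows for
bicarbonate, sulfate, bisulfide and methane are the regressed sets of the
standard aqueous-species compilations (Shock & Helgeson 1988, 1990).
Formate and the oxalate dianion lack fully regressed entries accessible
to this package: their reference-state values come from the published
compilations (Shock & Helgeson 1990; NBS tables, with the oxalate value
consistent with the known oxalic-acid pKa2), while their `omega`, `c1`,
`c2` and `a1` are derived from the Shock--Helgeson correlations with
charge, entropy, heat capacity and partial molal volume, and their
volumetric temperature dependence is simplified to a constant
nonsolvation volume. The oxalate heat capacity (-270 J mol^-1 K^-1) and
volume (25 cm^3/mol) are themselves systematics-based estimates
(bracketed by sulfate and carbonate) with uncertainties of order
30 J mol^-1 K^-1 and 5 cm^3/mol; propagated over the engine's
temperature range this contributes up to a few tenths of kJ/mol to the
oxalotrophy reaction energy, concentrated at the hot, high-pressure
corner of the grid. The species table is versioned data: replacing a row
with a better-regressed set requires no code change.

Activity corrections follow `dG_r = dG0_r + R T lnQ` with
`R = 8.3145 J/(mol K)` and `Q` the product of molal activities raised to
stoichiometric coefficients; activities are user inputs (no speciation or
activity-coefficient model, matching the survey's usage). A remark on
published values: with unit water activity, 10 uM formate, 2 mM
bicarbonate and 1--10 uM oxalate at 100 °C, the closed form gives
activity-corrected energies near -45 and -52 kJ/mol; isolated published
figures of "38.8" and "-41.1" kJ/mol for these conditions are not
reproducible from the stated standard-state value via the mass-action
relation and are treated as erratic. Likewise, where prose and table
disagree on the 1.01 vs 250 bar pairing of the 100 °C oxalotrophy
values, the table is taken as authoritative.

Verification is dual-route: the closed-form antiderivatives implemented
in R are checked against an independently written numerical-quadrature
route through the same equation of state (entropy and volume integrals
evaluated with adaptive quadrature and numerically differentiated Born
functions); 42 frozen species-level values agree to better than 1e-5
kJ/mol, against a test tolerance of 0.05 kJ/mol. At the reaction level
the engine reproduces the published 2--100 °C x 1.01/250 bar grid for
both reactions to within about 0.45 kJ/mol at atmospheric pressure; at
the 100 °C / 250 bar corner the residual reaches about 0.5 kJ/mol, which
is the expected imprint of the estimated oxalate volumetric parameters
described above.

## Synthetic data

The generator produces the statistical structure the analysis assumes,
not realistic molecular evolution. A family is built from a sampled
ancestor; group consensus sequences diverge from it by an independent
per-site substitution probability (`group_divergence`, default 0.3);
records scatter around their group consensus (`within_noise`, default
0.02); key sites are then forced to a specified residue with probability
`c` per record, else substituted; and a configured fraction of records
is truncated by replacing a random prefix or suffix with gaps (MAG-like
records, labelled as such in the metadata). Substitutions are uniform
over the 19 alternative residues — no empirical substitution matrix, no
indels, no rate heterogeneity — which is sufficient for the contracts
being tested (conservation recovery, clade structure, filter truth) but
means passing tests say nothing about model adequacy on real alignments.
Group labels double as taxonomy and source environment, giving the
perfectly label-partitioned clades the concordance statistic should
detect. Truncated records retain at least `min_kept_fraction` of their
length (default 1/3); for tree-building demonstrations the analysis
scripts raise this to 0.7, since two oppositely-truncated fragments that
retain under half their length each may share no comparable columns, in
which case the p-distance is undefined by design.

Hit tables are generated so each row passes both retention rules or
violates exactly one designated rule, giving exact expected counts. All
generators require a seed, are byte-reproducible, and emit truth records
sufficient to compute every downstream expectation without re-deriving
the generator.

## Test problem sizes

The suite keeps fixtures at desk scale as the package's own choice of
test design: conservation oracles run on random alignments up to 20 x 100
with a brute-force recount; NJ exactness on 50 seeded additive matrices
of 4--12 taxa; conservation recovery on 200-record families at
`c = 0.5, 0.9, 1.0` with a three-binomial-standard-deviation band;
bootstrap concordance on a 16-tip two-clade family at 500 replicates; the
energetics grid on the standard eight conditions. The full suite runs in
well under a minute.

## Known limitations

- The NJ path is intended for desk-scale trees (hundreds of tips); the
  O(n^3) agglomeration is pure R.
- No alignment is performed; gapped FASTA input is trusted as aligned.
- The energetics engine is not a general geochemical speciation code: no
  activity coefficients, no minerals or gases, no conditions beyond
  100 °C / 500 bar, and the two estimated oxalate parameters carry the
  uncertainty described above.
- Concordance purity is descriptive; it is not a test statistic with a
  null model.
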