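---
title: "Bin-marker linkage mapping and QTL scanning in full-sib families: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-marker linkage mapping and QTL scanning in full-sib families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `sibmap`, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the underlying
procedures were genuinely open. It states no empirical result that the
package's test suite and acceptance script do not themselves compute.

## The CP (pseudo-testcross) setting

A full-sib family from two outbred, heterozygous parents segregates at
three kinds of bi-allelic site: one parent heterozygous (`lmxll` when
the maternal parent is, `nnxnp` when the paternal parent is; both
segregate 1:1) and both heterozygous (`hkxhk`, 1:2:1). Each parent's
meioses form a separate mapping population; `hkxhk` markers see both
meioses and bridge the two parental maps.

**Parental-role convention.** `sibmap` codes `lmxll` as *maternal*
heterozygous and builds the maternal map from `{lmxll, hkxhk}`, the
paternal map from `{nnxnp, hkxhk}`. The `swap_parents` flag of
`classify_segregation()` flips the roles for data sets coded the other
way around; the downstream machinery is symmetric.

## Site quality and segregation filtering

Calls whose read support lies outside `[4, 200]` become missing; the
bounds are retained (a call at exactly 4 or exactly 200 passes).
Progeny calls impossible under the parental genotypes (the opposite
homozygote under het x hom) are set missing and counted; a site whose
impossible-call rate exceeds 5% (configurable) is rejected, since such
sites usually indicate a mistyped parent. Segregation is tested by a
Pearson chi-square against 1:1 (df 1) or 1:2:1 (df 2) with missing
calls excluded; sites are rejected under the strict rule `P < 0.05`, so
a site at exactly the threshold survives.

## The five-step bin-marker algorithm

Within one segregation set and chromosome, with physical tiles of
`window_bp` (default 500 kb, the study-scale choice; the tool's
historical default was 10 kb):

1. per tile and progeny, the call is the majority CP code over
   non-missing member SNPs; exact ties and empty cells are missing;
2. a missing call is filled with the strict majority of the `k` nearest
   non-missing window calls (default 2 per side). The scope of this
   "majority rules" fill was not pinned down by its source; the
   window-level nearest-neighbor interpretation is ours, configurable,
   and `k_side = 0` disables the step;
3. a maximal missing run whose two flanking calls are non-missing and
   identical is filled with that call;
4. a call differing from both its immediate neighbors is replaced when
   the neighbors are non-missing and identical (singleton smoothing);
5. maximal runs of adjacent tiles with element-wise identical genotype
   vectors merge into one bin; by default missing matches missing
   (required to reproduce long merged bins; `na_matches_na = FALSE`
   demands fully observed identity). The bin span is clipped to the
   member-SNP extremes and member counts are summed.

Steps are applied in order, one pass each, and adjacency is tile order
(radius configurable). Tiles are physical-coordinate tiles, not
SNP-count tiles. The test suite checks the pipeline cell-for-cell
against an independent brute-force implementation of these rules on
random matrices.

## Two-point recombination analysis

For a marker pair the joint genotype table is a mixture over the
(at most 16) latent transmission configurations of the two parental
meioses; a parent contributes recombination information only when it is
heterozygous at both loci. The likelihood coefficients are enumerated
once per (type pair, phase configuration) and cached; EM then maximizes
the likelihood in `r`, vectorized across all pairs of a type combo at
once, and the reported estimate is the maximum over admissible
coupling/repulsion phase configurations (at most 4). For fully
informative same-parent pairs this reduces to
`r = min(f, 1 - f)` with `f` the mismatch fraction; mixed (`lmxll x
hkxhk`) and `hkxhk x hkxhk` tables genuinely need the EM because the
`hk` class is ambiguous. `lmxll x nnxnp` pairs share no meiosis: `r` is
inestimable and, the meioses being independent, their independence LOD
is near zero — which is what keeps the two parental data sets apart
during grouping.

Reported alongside `r`: the linkage LOD `log10 L(r)/L(0.5)` and an
independence LOD defined as `G^2 / (2 ln 10)` from the likelihood-ratio
independence test of the joint table (the grouping threshold names a
statistic but not a formula; this is the JoinMap-style choice).

Pairs with fewer than `min_joint = 20` jointly observed progeny are
unusable; pairs below `min_lod_edge = 3` linkage LOD are excluded from
the ordering objective (the "weak linkage" exclusion surfaced as an
explicit parameter).

## Grouping, ordering, and map distances

Markers with more than `max_missing = 9` missing calls are excluded
first. Groups are connected components of the graph with edges at
independence LOD at least `ind_lod_min = 9`; a threshold ladder (2-30)
is reported for diagnostics. Distances are Kosambi,
`d = 25 ln((1+2r)/(1-2r))` cM.

**Ordering objective.** Given a candidate order, inter-marker gaps are
fitted by weighted least squares against *all* pairwise two-point
distances, and the objective is the weighted residual sum of squares —
regression mapping in the literal sense. Weights are delta-method
inverse variances of the Kosambi distance estimate,
`(1 - 4r^2)^2 / (r(1-r))`, gated by the minimum-LOD edge filter. Two
details here deviate deliberately from the simpler textbook recipe
(raw-LOD weights, cumulative adjacent distances): near-independent
pairs have Kosambi distances with enormous sampling variance, and
raw-LOD weighting lets them dominate the fit; and cumulative adjacent
two-point distances inflate severely under genotyping error, penalizing
the true order by its own inflation. Fitting the gaps inside the
objective removes both pathologies, and the final map positions are the
fitted (non-negative) gaps of the final order.

**Search.** Greedy insertion seeded from the strongest pair, plus a
principal-coordinate (classical MDS) seriation start and a
shortest-path polish of it; the best candidate under the objective is
then polished by 2-opt segment reversals and or-opt relocations of
short segments to a local optimum. A clean-up pass excludes markers
whose mean weighted residual exceeds `resid_drop = 4` times the group
median (bounded at 20% of the group) and re-polishes — the programmatic
analogue of the manual practice of dropping loci that fit the map
poorly. The ordering heuristic is validated against exhaustive
enumeration on 5-marker groups.

Markers whose nearest within-group neighbor exceeds `nn_r_max = 0.15`
are left out of the ordered parental maps as weakly linked; window bins
corrupted by near-tie majority votes show exactly this signature.

## Consensus maps

Parental linkage groups pair by shared (`hkxhk`) bridge markers. With
at least two bridges, an isotonic (monotone piecewise-linear) alignment
is fitted through the bridge position pairs; the group whose
bridge-anchored span is larger provides the consensus axis — a
consensus map should not be shorter than its parents — and the other
group's markers are projected through the alignment, with linear
extrapolation beyond the terminal bridges. Position ties are broken by
the LOD-weighted mean rank across the two parental orders. With fewer
than two bridges the union of both groups' markers is re-grouped and
re-ordered jointly (this fallback needs the bin genotypes). Unpaired
groups are carried through unchanged with a warning, and all consensus
positions are rescaled to start at zero.

## Transmission probabilities and QTL scans

For each parent a two-state hidden Markov chain runs along every
linkage group: states are the parental haplotypes, transitions the
inverse-Kosambi fractions of the inter-position distances, emissions
match the parent's informative markers with miscall rate `eps`
(default 0.01). Relative marker phases along the chain come from the
adjacent-pair maximum-likelihood phases. For `hkxhk` emissions the
other parent's transmission is marginalized uniformly, which keeps the
two chains independent; their outer product gives the four transmitted
classes AC/AD/BC/BD, normalized by construction.

Interval mapping regresses the (transformed) trait on the expected
class indicators — three contrasts — at every grid position
(Haley-Knott style; mixture-EM is an extension point, the regression
version being deterministic and fast at this LOD scale), with
`LOD = (n/2) log10(RSS0/RSS1)`, the fixed genome-wide threshold 2.5,
PVE `100 (1 - RSS1/RSS0)` at the peak, and support intervals by walking
the curve down 1 or 2 LOD units. Reported peaks are local maxima at
least 10 cM apart — reusing the cross-environment adjacency tolerance,
since no within-scan peak-merging rule was stated. One caveat worth
stating plainly: with three contrasts, a single position exceeds LOD
2.5 under the null with probability about 0.9%
(`P(chi2_3 > 2 ln(10) 2.5)`), so the genome-wide null exceedance rate
of this fixed threshold is necessarily above 5% for any multi-group
scan; the acceptance suite measures it as such rather than pretending
otherwise.

The Kruskal-Wallis scan applies the tie-corrected test per marker over
its genotype classes (at least two classes with two observations each),
with the stringent significance level 0.005. Peaks from two
environments match when on the same group and strictly closer than
10 cM (greedy nearest pairing). Support intervals project to physical
intervals through the bins' spans, merged per chromosome, optionally
intersected with a GFF3 gene annotation.

**Heritability.** Marker transmissions are coded as centered maternal-
and paternal-allele indicator columns (the ambiguous `hk` class at its
expectation 0.5), the GRM is scaled to mean diagonal 1, and
`y = mu + g + e` with `g ~ N(0, sigma_g^2 G)` is fitted by REML via the
spectral decomposition of `G` and a one-dimensional search over the
variance ratio; `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`. Rank
deficiency of `G` is expected and harmless; only an indefinite matrix
triggers a ridge (with a warning). The PVE of a QTL peak is RSS-based
as defined above — the upstream software's exact definition is
unpublished, so ours is stated and tested as such.

## Collinearity and scaffold re-anchoring

A SNP of one map pairs with a bin of another within the bin's physical
span (`within_bin`, nearest on ties), else on a shared scaffold
(`same_scaffold`); pairs are concordant when their linkage groups
correspond to the same chromosome by majority vote. Against a
reference anchoring, mapped markers classify as co-anchored, misaligned
or new-anchored (scaffold unanchored), with collinearity
`100 co/(co + mis)` — the classes partition the classified markers.

Re-anchoring assigns each scaffold the marker-count-weighted majority
linkage group across the supplied maps (per-map weights default equal —
how conflicting maps were weighted originally is unstated), orders
scaffolds by weighted mean cM, orients them by the sign of the
cM-versus-bp rank correlation (`?` with fewer than two distinct
positions, written as `+` in the AGP with a flag), and cuts a scaffold
at a bin-span edge when two runs of at least two markers each support
different groups — the run-length rule is ours; the source states only
that scaffolds were cut at bin edges. AGP v2.1 is emitted with fixed
100-bp `U` gaps (`scaffold`/`yes`/`map`), validated for contiguity and
alternation, and round-trips through the bundled reader.

## The synthetic-data generator

Each parental meiosis is a two-state Markov chain along the true map
with transition probabilities from the inverse map function (Kosambi by
default) of the inter-marker spacing — pairwise recombination only, no
crossover interference, which matches the two-point theory used
downstream. Observed genotypes apply a uniform miscall (default 1%)
then missingness (default 5%); per-call support is negative binomial
(mean 14, size 5, matching ~14x resequencing depth) and exists to
exercise the masking rule. Defaults are study-like: 176 progeny, 17
chromosomes (~30 Mb / 80 cM), segregation mix 43/42/15% for
lmxll/nnxnp/hkxhk.

**Phase coherence.** Real resequencing of a cross aligned to a
reference closely related to the parents places alternate alleles
predominantly on the non-reference haplotype: the heterozygous parent's
alt allele sits on haplotype 2, and the homozygous parent is hom-ref,
each with probability `phase_coherence` (default 0.85). This matters:
with fully random phases (0.5) the majority vote inside a window
acquires an arbitrary orientation per window, the cross-window
imputation and singleton-correction steps then mix incompatible
orientations, and bin genotypes degrade in a way no downstream method
can repair. The default encodes the study system, where the reference
cultivar is a close relative of the cross (progeny read-mapping rates
around 94%); `phase_coherence = 0.5` remains available to study the
failure mode itself.

What the generator does **not** emulate: linkage disequilibrium
structure and allele-frequency spectra of real germplasm, sequencing
reads themselves (support counts are parametric), crossover
interference, segregation-distortion loci, structural variation, or
reference bias in alignment. Passing tests therefore demonstrate the
correctness and statistical behavior of the chain under its stated
model, not robustness to every artifact of real resequencing data.

Traits are sums of QTL class effects (4-vector over AC/AD/BC/BD at a
planted position), a polygenic term built from small random effects on
every marker's transmissions, and Gaussian noise, each rescaled so
realized variance fractions equal their targets (total variance 1). A
PVE sum of exactly 1 is allowed — it yields the deterministic noise-free
trait used in tests. Genome fragmentation cuts chromosomes at uniform
positions, misassigns a configurable fraction of scaffolds in the
"reference" (wrong chromosome, flipped orientation, or both) and leaves
a further fraction unanchored (default 25%, emulating the ~40%
new-anchored markers a draft assembly shows); the true AGP is retained.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale, chosen once: unit
populations of 40-100 progeny on 1-2 chromosomes; study-condition
suites with 176 progeny on 3-5 chromosomes of 7.5 Mb / 80 cM with 900
SNPs each (15 windows per chromosome per set, roughly 20 SNPs per
window — enough for stable majority votes at the default phase
coherence). Ten seeds back the map-recovery suite; 100 null and 50
planted replicates back the scan calibration; 50 seeds back the
heritability recovery; 50 scaffolds with 20% misassignment back the
anchoring suite, on a ten-chromosome (800 cM) genome so that each
scaffold carries a study-like genetic span (~16 cM; orientation cannot
be resolved for scaffolds spanning less map than the per-marker cM
jitter), evaluated over scaffolds carrying at least three markers. Degenerate inputs are handled explicitly: zero-length groups,
single-marker groups (interval undefined, reported empty), constant
traits (Shapiro-Wilk flagged), all-tied Kruskal-Wallis samples (H = 0),
empty support intervals, scaffolds without markers (left unplaced).
EM iterates to `1e-10` with `r` clamped to `[1e-9, 0.5]`; the gap-fit
normal equations carry a `1e-8` ridge; positions are non-negative by
clamping fitted gaps at zero.

## Known limitations

- Ordering is two-point based; multipoint likelihood ordering (and
  bit-compatibility with JoinMap/MergeMap) is out of scope.
- The fixed LOD 2.5 threshold is anticonservative for a 3-contrast scan
  (see above); permutation thresholds are a natural extension.
- The consensus alignment assumes locally monotone parental maps; maps
  with large-scale inversions between parents would need the fallback
  path.
- Heritability assumes a purely additive polygenic architecture through
  the transmission-indicator GRM.
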