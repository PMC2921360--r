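---
title: "Mapping proteinase cleavage sites and subsite specificity with scissile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping proteinase cleavage sites and subsite specificity with scissile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scissile)
```

## The scientific problem

Blood-feeding parasites digest host hemoglobin inside acidic digestive
vesicles using a network of aspartic (cathepsin D-like) and cysteine
(cathepsin L-like) endopeptidases. The fragments this digestion releases
include *hemocidins* — hemoglobin-derived peptides with antimicrobial
activity that are thought to help control the midgut flora. Characterizing
which enzyme cuts where, and with what subsite preference, therefore ties
enzymology directly to innate immunity.

`scissile` implements the computational side of that characterization as a
reusable, fully testable pipeline:

1. **Cleavage-site inference from tagged substrates.** Internally quenched
   fluorogenic substrates carry an N-terminal ortho-aminobenzoic acid (Abz)
   fluorophore and a C-terminal ethylenediamine-2,4-dinitrophenyl (EDDnp)
   quencher. After digestion, LC/MS ion lists are matched against the
   theoretical masses of all candidate fragments, and each matched fragment
   identifies a scissile bond.
2. **Degradome profiling.** Product peptides identified after digestion of
   hemoglobin are mapped back onto the parent chains; every internal
   peptide terminus evidences a cleavage site, and the residues flanking
   each site are tabulated in Schechter–Berger subsites (P4…P1 on the
   N-terminal side of the bond, P1′…P4′ on the C-terminal side).
3. **PS-SCL profiling.** Positional-scanning synthetic combinatorial
   library rates are normalized per subsite and condensed into a
   specificity matrix, which can also drive in-silico digestion and be
   compared quantitatively against degradome-derived preferences.
4. **Kinetics.** Initial rates, specific activities, inhibitor comparisons
   (Welch's t-test at p ≤ 0.05), pH optima and apparent first-order
   thermal-inactivation constants.

A seeded synthetic-data module emulates every input, so the full pipeline
is exercised end-to-end in the test suite without any external downloads.

## Mass conventions

Two mass conventions deliberately coexist:

* **monoisotopic** residue masses are the default for fragment matching,
  because that is the natural scale for ion-trap peak lists;
* **average** masses are used for whole-protein kDa figures, the
  convention for predicted protein masses.

Published "theoretical m/z" values for small fragments are, in practice,
an inconsistent mixture of the two (and of rounding conventions). The
default matching tolerance of **0.5 Da** absorbs this: it is wide enough
for unit-resolution instruments and for the mono/average discrepancy on
fragments below ~1 kDa, yet narrow enough that candidate fragments of a
short substrate rarely collide. The tolerance is a visible parameter of
`match_ions()` and is echoed into every report.

Terminal tags are fixed composition deltas applied exactly once per
terminus: Abz acylation adds C7H5NO (+119.037 Da monoisotopic) to the
N-terminal amine; EDDnp amidation replaces the C-terminal hydroxyl with
C8H9N4O4 (net +208.060 Da). With these compositions the theoretical
singly protonated masses of the worked-example fragments (FLSQ-EDDnp
702.32, Abz-LERMFL 927.48, AALTQQ-EDDnp 839.40, QQ-EDDnp 483.19, AALT
375.44 in average mode) land within 0.13 Da of their published values.

The isoelectric point is computed by bisection on the Henderson–
Hasselbalch net-charge function. Because the result depends materially on
the pKa constants chosen, the pKa set (`"emboss"` default, `"expasy"`
alternative) is always reported alongside the value, and the package
treats literature pI figures as soft checks only.

## Ion matching: why internal fragments are confirmatory

```{r}
sf57 <- tagged_substrate("SF 57-67", "GHGAKVAAALTQQ", "Abz", "EDDnp",
                         parent_offset = 57)
match_ions(sf57, c(839.5, 483.2, 374.5), tolerance = 0.5, max_cuts = 2)
```

Matching proceeds in two stages. Tag-retaining fragments (the products of
a single cut) are matched first: each carries either the fluorophore or
the quencher, so its mass pins the cut to exactly one bond. Untagged
internal fragments — products of two simultaneous cuts — are then matched
only against cut *pairs already evidenced* by tagged fragments.

This staging is not cosmetic. A short untagged fragment mass is compatible
with many substring placements: in the substrate above, an ion near
374.5 m/z lies within 0.5 Da of the internal fragment GAKV (374.24) as
well as near AALT (375.22), and a naive nearest-mass assignment would
invent two cleavage sites that nothing else supports. Treating internal
fragments as confirmatory reproduces how such spectra are actually
interpreted: the doubly cut fragment corroborates sites established by the
tagged ions and can never introduce new ones. Ions that fit no acceptable
fragment are reported as unassigned rather than discarded silently, and
exact ties are flagged ambiguous rather than resolved arbitrarily.

## Degradome statistics

Coordinates are 1-based inclusive on the mature chain, and a scissile bond
is indexed by its N-side residue, so the bond written Met32/Phe33 has
position 32, P1 = Met32 and P1′ = Phe33. Peptides located at more than
one position are flagged ambiguous and excluded from site extraction by
default (`strict = TRUE`); a permissive mode counts every occurrence.
Sites are supported by however many peptide termini evidence them, and
`min_support = 1` is the default because single-peptide evidence is
routinely accepted in degradome maps.

Subsite columns truncated by a chain end are tracked separately, so
percentages are always taken over the residues actually observed. The
residue polarity partition behind class percentages (non-polar =
{A, V, L, I, M, F, W, P, G}) is an explicit, configurable convention —
published degradome percentages rarely state theirs, so ours is declared
in the report rather than hidden.

Hemocidin annotation compares each mapped peptide against a packaged
reference of hemoglobin fragments with reported antimicrobial activity:
exact interval identity means `known_antimicrobial`; a positional Jaccard
overlap of at least 0.5 (default) means `potential_antimicrobial`. The
0.5 default requires the candidate to share the majority of its span with
a known active fragment, which is deliberately conservative for short
peptides.

## Specificity matrices and in-silico digestion

A specificity matrix holds per-subsite weights max-normalized to 1.
Residues absent from a library panel carry `NA` ("no information"), which
is distinct from a measured weight of zero ("forbidden") — PS-SCL panels
commonly omit cysteine, and conflating the two would fabricate a veto.

`predict_cleavage()` scores every internal bond. The default combination
rule is **min** over covered subsites: a single forbidden residue blocks
cleavage. This mirrors observed papain-family behaviour — a proteinase
that does not accept Ala at P2 will not cut a bond with Ala at P2 no
matter how favourable P1 is — and it makes the rule's vetoes auditable:

```{r}
hb <- bovine_hemoglobin()
m <- specificity_matrix(list(P2 = c(A = 0, V = 1, L = 0.8, F = 0.6),
                             P1 = c(R = 1, K = 0.6, Q = 0.5, M = 0.4)))
pred <- predict_cleavage(hb[1, ], m)
pred$bonds[pred$bonds$position == 61, ]  # Lys61/Val62 has Ala at P2
```

`product` and `mean` rules are available for graded scoring. Subsites
that fall off a chain end are *skipped*, not scored zero — otherwise every
near-terminal bond would be forbidden by construction. The prediction
threshold (default 0.5) is stored in the matrix and echoed in every
output.

`concordance()` compares a matrix against observed sites by per-subsite
Spearman rank correlation plus top-3 residue-set overlap. Rank correlation
over a 20-residue panel has a null standard deviation of about 0.23, so
single-subsite values are noisy by nature; the mean across subsites is the
more stable summary and is attached to the result.

## What the synthetic generators do and do not emulate

The generators produce data with the statistical structure each stage
assumes, with a mandatory seed and scoped RNG use (caller state is
restored):

* `gen_digest()` cuts each bond independently with probability
  `scale × score` and thins the resulting peptides by detection dropout
  and a minimum length — a partial digest with loss, whose ground-truth
  cut set is returned alongside the observations. Under the `product`
  rule on a uniform random parent, observed subsite frequencies are
  proportional to matrix weights, which is the regime the recovery tests
  use.
* `gen_psscl()` draws rates proportional to weights with multiplicative
  Gaussian noise truncated at zero.
* `gen_decay()` simulates apparent first-order inactivation; `gen_ions()`
  perturbs theoretical fragment m/z values with Gaussian mass error.

They do **not** model ionization efficiency, intensity, isotope envelopes,
missed-cleavage correlation along a molecule, or cooperative subsite
effects. Passing the recovery tests therefore shows that the estimators
invert the assumed generative model correctly — not that real spectra are
free of the biases these simplifications ignore.

## Numerical choices and degenerate inputs

* Inactivation fitting is a log-linear regression (slope of ln activity
  vs time), matching the straight-line presentation of apparent
  first-order kinetics; non-positive readings are excluded with a warning
  and a constant series yields k1 = 0 with an infinite half-life. The
  constant is held per minute (half-lives are quoted in minutes) with the
  per-second value alongside.
* Welch's unequal-variance t-test is the default two-sample procedure:
  it is the safer interpretation when only "Student's t test" is stated
  and replicate variances differ.
* Fold ratios offer an `"order"` reporting mode (nearest ten) for
  order-of-magnitude statements such as a 40-fold activity difference.
* pH optima report ties as a range rather than picking a winner.
* Empty inputs produce empty, schema-valid outputs; malformed rows become
  per-row error records (coordinate mismatches) or errors naming the file,
  column and row (non-numeric m/z), never silent coercion.

## Problem sizes used in the checks

The property suite runs synthetic digests of random parents of 1,500–4,000
residues (giving several hundred to ~2,000 cleavage sites), 200-seed
kinetics recovery ensembles and a 1,000-seed ensemble for the half-life
recovery bound, 30–100-seed ensembles for PS-SCL noise bounds, and 40-seed
null ensembles for concordance. These sizes put the Monte-Carlo error of
each asserted proportion well below the asserted margin while keeping the
whole suite in tens of seconds.

## Known limitations

* Only the two terminal tags plus C-terminal amidation are modelled; no
  other PTMs, no isotope envelopes, no charge states beyond a declared
  single charge by default.
* Peptide location is exact substring matching; I/L are distinct letters
  even though isobaric, so sequences reported with the wrong isobaric
  letter will not map.
* The pI depends on the pKa set and ignores conformational effects; it is
  a screening value, not a measurement.
* Specificity matrices are position-independent (no inter-subsite
  coupling), and in-silico digestion treats bonds independently — both
  standard, both simplifications.
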