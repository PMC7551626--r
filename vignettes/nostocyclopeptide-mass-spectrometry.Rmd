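---
title: "Topology-aware fragment prediction and structure elucidation for nostocyclopeptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-aware fragment prediction and structure elucidation for nostocyclopeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncptools)
```

## The problem

Nostocyclopeptides (Ncps) are heptapeptides from the cyanobacterium
*Nostoc* with an unusual head-to-tail macrocycle: the nonribosomal peptide
synthetase (NRPS) releases the chain reductively as a linear peptide
**aldehyde** (C-terminal -CHO instead of -COOH), and the aldehyde then
condenses spontaneously with the N-terminal Tyr amine to form a cyclic
**imine** (Schiff base), losing one water. A strain therefore produces
pairs of congeners — open-chain aldehydes and their macrocycles — that
differ by exactly 18.011 Da, plus sequence variants at a few positions.
Unit-resolution CID spectra from a triple-quadrupole/linear-ion-trap
instrument are the primary evidence for their structures, and assignments
are traditionally made by hand from b/y ions, ring-opened fragments and
immonium ions.

`ncptools` formalizes that desk work: a monomer registry with the
nonproteinogenic residues (4-methylproline, homoserine), topology-aware
precursor and fragment arithmetic, a peak-list annotator and scorer, a
candidate enumerator/ranker that reproduces the manual elucidation, a
substrate predictor for NRPS adenylation domains, and a seeded spectrum
simulator for benchmarking.

## Mass model

All arithmetic is monoisotopic. The constants (Da) are proton 1.00728,
H 1.00783, O 15.99491, H2O 18.01056, NH3 17.02655, NH2 16.01872,
CO 27.99491; residue masses derive from elemental formulas with IUPAC
atomic masses. Unit-resolution ("nominal") values are obtained by rounding
half away from zero, which reproduces every published integer m/z tested.

Neutral masses by topology, with $R$ the residue-mass sum:

* linear acid: $R + \mathrm{H_2O}$
* linear aldehyde: $R + 2\mathrm{H}$
* cyclic imine: $R + 2\mathrm{H} - \mathrm{H_2O} = R - \mathrm{O}$

so a macrocycle is always one water lighter than its open-chain aldehyde.
The immonium ion of a residue is defined as its acylium ion minus CO
(offset $\mathrm{CO} - \mathrm{proton} = 26.98763$ Da below the residue
mass). Defining it this way — rather than the also-common
"residue $- \mathrm{CO} + \mathrm{H}$", which differs by the 0.00055 Da
proton/H-atom gap — keeps the identity *immonium = acylium − CO* exact,
and changes no nominal value.

```{r masses}
reg <- monomer_registry()
a1 <- ncp_structures(reg)[["Ncp-A1"]]
c(neutral = neutral_mass(a1, reg),
  mh = precursor_mz(a1, 1, reg),
  nominal = nominal_mz(precursor_mz(a1, 1, reg)))
```

### The one discrepant congener

The free-acid hexapeptide Ncp-E4-L (Tyr+Gly+Gln+Ile+Ser+MePro, described
with a carboxyl C-terminus) computes to nominal [M+H]+ 678 by free-acid
arithmetic, while its published value is 677 — an amide C-terminus would
give 677, as would the published [M+H−H2O] 659 and [M+H−H2O−NH3] 642.
The package reproduces its own arithmetic and documents the conflict
rather than silently adjusting a terminus; all of the hexapeptide's
sequence-informative ions (b series, internals, diagnostics) are
terminus-independent and reproduce exactly.

## Fragment chemistry

For linear peptides the enumerator emits the b series
($b_i = \sum_{1..i} + \mathrm{proton}$), the y series with the structure's
C-terminal chemistry ($y_j = \sum_{n-j+1..n} + terminus + \mathrm{proton}$,
terminus = H2O or 2H), a ions ($b_i - \mathrm{CO}$), internal acylium
fragments, residue losses off the precursor, immonium/diagnostic ions per
distinct residue, and neutral-loss variants. $b_n$ is not emitted; it
duplicates precursor-derived species.

For cyclic imines, ring opening under CID yields acylium (b-type) ions
only: every contiguous ring span of length $1..n-1$ gives
$\sum span + \mathrm{proton}$, **minus one oxygen when the span contains
residue $n$**, whose carbonyl carbon is the imine CH. This −O rule is the
single piece of chemistry that distinguishes imine macrocycles from
ordinary cyclic peptides; it was validated against the published
ring-fragment series (e.g. [MePro+Leu+H] at 209 rather than 225).

Neutral-loss combinatorics allow multisets over {H2O (twice), NH3, CO}
with at most two combined losses by default — the deepest published
combination has two. Residue losses use topology-effective masses: plain
residue for interior/N-terminal positions, residue+2H for the aldehyde
terminus, residue−O for the imine-carbon residue of a macrocycle.

Equivalent species produced by different routes (a ion vs b−CO; a
residue loss whose surviving complement is a contiguous b/y span or ring
span) are de-duplicated on (composition, span start, m/z at 1e-4 Da),
keeping the higher-priority family. Because of this, a span acylium that
touches the C-terminus (such as the hexapeptide's Ile+Ser+MePro at 312)
appears once, as the water-loss form of the corresponding y ion — same
exact mass, one row.

```{r fragments}
e1 <- ncp_structures(reg)[["Ncp-E1"]]
th <- cyclic_fragments(e1, registry = reg)
th[th$residues == "Pro+Phe" & th$n_losses == 0, c("kind", "label", "mz", "nominal")]
```

## Matching and scoring

Peaks are assigned to theoretical ions greedily in ascending absolute
error, with ties broken by fewer losses, then kind priority
(b > y > a > internal > residue-loss > precursor-loss > diagnostic), then
lower span start. Each peak takes at most one ion and each ion is consumed
once; on peak lists spaced more than twice the tolerance apart this greedy
scheme provably attains the exhaustive maximum-cardinality matching (the
match graph decomposes into disjoint stars), which the test suite verifies
against a brute-force matcher.

Two scores are reported: `score_intensity` (explained fraction of total
intensity, the primary score — robust to small decoy peaks and consistent
with reading spectra by their most intense ions) and `score_count`
(explained fraction of peaks). The default tolerance of **0.5 Da** is a
declared setting for unit-resolution ion-trap spectra, not a published
value; it is configurable per run.

The cyclization extent metric is plain arithmetic,
`cyclic_linear_ratio(cyclic, linear) = 100 * cyclic / linear` percent;
the raw chromatographic intensities behind the published ratios are not
reprinted anywhere, so only the operation's contract is testable.

## Candidate elucidation

The congeners vary at positions 4 (Ile/Val), 6 (MePro/Pro) and 7
(Leu/Phe) of a conserved scaffold — exactly the positions whose
adenylation domains have multi-substrate codes. `ncp_template()` spans
those sets in both open-chain-aldehyde and cyclic-imine topologies
(16 candidates); `rank_candidates()` scores each candidate's theory
against the observed peaks and sorts by intensity score, count score,
parsimony (fewer theoretical ions), then residue string. Ile and Leu are
isobaric and indistinguishable at unit resolution, so Ile/Leu-swapped
candidates are collapsed into one equivalence class by default.

The hexapeptide congener necessarily sits outside the heptapeptide
template; for its recovery benchmark it is appended to the candidate set
as a 17th candidate. The foreign-strain congener Ncp-M1
(cyclo[Tyr+Tyr+HSe+Pro+Val+MePro+Tyr]) has a different scaffold altogether
and is included in the structure table for mass computation only.

## Adenylation-domain code

Substrate prediction is a nearest-neighbour lookup over 9-residue
binding-pocket signatures (GrsA numbering 235–331), scored by plain
identity fraction — deliberately not a substitution-matrix or HMM score,
since the nonribosomal consensus code is applied as a lookup; a matrix can
be passed for weighted scoring. The packaged reference is the seven
synthetase modules of the studied strain with their proposed substrates,
clearly self-referential: it validates the code round-trip and gives users
a seed table to extend with published codes via TSV.

## The spectrum simulator

`simulate_spectrum()` stands in for raw LC-MS/MS data, which is not
printed in any table. Its defaults are a declared model of
unit-resolution CID acquisition: each theoretical ion survives with
probability 0.8 (dropout 0.2), m/z jitter is Normal(0, 0.1 Da) against a
0.5 Da matching tolerance, intensities are log-normal (meanlog log(1e4),
sdlog 1) with a 5x boost for ions spanning only the two C-terminal
residues (these dominate real Ncp spectra), and 5 uniform decoy peaks are
drawn over the 50–1000 m/z product-ion range with intensities from the
lower quartile of the peak model. All draws derive from an explicit seed
(default 1411, the strain collection number — arbitrary); the same seed
reproduces byte-identical fixtures.

What the simulator does **not** emulate: isotope envelopes, charge states
above +1, collision-energy-dependent intensities, retention-time
structure, and correlated chemical noise. Passing the recovery benchmarks
therefore shows that the scoring separates congener hypotheses under
peak dropout, mass error and sparse decoys — not that it would survive
co-eluting isobaric contaminants in a real matrix.

## Numerical and design choices

* Rounding: half away from zero to integer nominal m/z.
* Tolerance: 0.5 Da default; matching is monotone in tolerance (tested).
* Degenerate inputs: empty spectra, empty candidate sets, empty position
  sets, malformed structure strings and unknown residue tokens all raise
  informative errors; an empty theoretical list yields zero scores rather
  than an error.
* Linear structure strings default to the aldehyde terminus with a
  warning, because all open-chain heptapeptide congeners are aldehydes
  and a silent acid default would mis-parse them; free-acid input must
  say so explicitly.
* Ranking tie-breaks are fixed and documented; the manual elucidation
  they formalize had no explicit score, so the comparator is a declared
  convention, and both scores are always reported side by side.

## Problem sizes

The shipped analyses and tests run at the study's natural scale: 11
structures of 6–7 residues, theoretical ion tables of roughly 200–400
ions, peak lists of 19–25 published ions, a 16–17 candidate template,
recovery benchmarks of 10–20 noisy replicates per congener, and 200-seed
statistics for the simulator's expected peak count.

## Limitations

* The fragment model covers b/y/a/internal/ring/residue-loss/diagnostic
  families with up to two neutral losses; c/z and x ions, multiply
  charged fragments and Na/K adducts are out of scope.
* Elucidation is template-constrained, not unrestricted de novo
  sequencing over the full residue alphabet.
* Signature extraction from raw A-domain protein sequence (alignment to
  GrsA) is excluded; queries enter as 9-mers.
* The residue-mass table is standard biochemistry; the source spectra
  never print residue masses, so the table is validated against elemental
  formulas, not against the publication.
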