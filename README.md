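# ncptools

Mass-spectrometry toolkit for the structure elucidation of
**nostocyclopeptides** (Ncps) — *Nostoc* heptapeptides whose C-terminal
aldehyde condenses with the N-terminal Tyr amine into a head-to-tail
**imine macrocycle** — and, more generally, for nonribosomal peptides with
nonproteinogenic residues such as 4-methylproline (MePro) and homoserine
(HSe). It is written for natural-product and peptide mass spectrometrists
who read unit-resolution CID spectra and want the manual b/y/immonium
bookkeeping, candidate ranking and NRPS substrate-code lookups done
reproducibly in code.

## The model

All arithmetic is monoisotopic. With $R$ the sum of residue masses, the
three topologies are:

| topology | neutral mass | chemistry |
|---|---|---|
| linear acid | $R + \mathrm{H_2O}$ | conventional peptide |
| linear aldehyde | $R + 2\mathrm{H}$ | reductase-released open chain (-CHO) |
| cyclic imine | $R - \mathrm{O}$ | Schiff-base macrocycle (aldehyde − H2O) |

Fragments: $b_i = \sum_{1..i} + p$, $y_j = \sum_{n-j+1..n} + t + p$
($t$ = H2O or 2H, $p$ = proton), $a_i = b_i - \mathrm{CO}$, internal
acylium ions, residue losses off [M+H]+, immonium/diagnostic ions, and up
to two combined neutral losses over {H2O, NH3, CO}. Ring opening of a
cyclic imine yields acylium ions for every contiguous ring span, **minus
one oxygen whenever the span contains the imine-carbon residue** (position
$n$) — the signature arithmetic of this peptide family. Observed peaks are
assigned greedily one-to-one within a 0.5 Da tolerance and candidate
structures are ranked by explained-intensity fraction, with Ile/Leu
(isobaric) candidates collapsed into equivalence classes.

Adenylation-domain substrates are predicted by identity over the
nine binding-pocket residues (GrsA numbering 235–331) against a packaged
reference of the seven Ncp synthetase modules.

## Worked example

```r
library(ncptools)
reg <- monomer_registry()

s <- parse_structure("cyclo[Tyr+Gly+Gln+Ile+Ser+MePro+Leu]",
                     name = "Ncp-A1", registry = reg)
precursor_mz(s, 1, reg)          # 757.4243  -> nominal 757
th <- cyclic_fragments(s, registry = reg)
th[th$residues == "MePro+Leu" & th$kind == "b", c("label", "mz", "nominal")]
#>                label       mz nominal
#>        [MePro+Leu+H] 209.1648     209
#>     [MePro+Leu+H-CO] 181.1699     181
#>    ...
```

The [MePro+Leu+H] span crosses the imine junction, so it is one oxygen
lighter than plain acylium arithmetic: 209, with its CO-loss companion at
181 — the diagnostic pair for a MePro-Leu C-terminus (the Pro homolog
shifts both down 14 to 195/167).

Ranking the published 20-peak product-ion list of the open-chain congener
against the 16-candidate template (positions 4/6/7 variable, both
topologies):

```r
sp <- read_peaklist(system.file("extdata", "ncp_e1l_ions.txt", package = "ncptools"))
rank_candidates(sp, ncp_template(), registry = reg)
#>  rank                          structure        topology score_intensity score_count
#>     1        Tyr+Gly+Gln+Ile+Ser+Pro+Phe linear-aldehyde            1.00        1.00
#>     2 cyclo[Tyr+Gly+Gln+Ile+Ser+Pro+Phe]    cyclic-imine            0.90        0.90
#>     3 ...
```

Every peak is explained by the true open-chain aldehyde; its macrocycle
(18 Da lighter) trails because the aldehyde-specific y ions go
unexplained. Substrate lookup for an A-domain signature:

```r
predict_substrate("DVWHISLID")
#>  module substrate similarity
#>   NcpB2       Ser  1.000
#>   NcpA3       Gln  0.556
#>   NcpA2       Gly  0.333
```

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each writing its
tables under `results/`:

1. `01_precursor_masses.R` — neutral and [M+H]+ masses for all congeners.
2. `02_annotate_spectra.R` — per-peak annotation of the published
   product-ion lists (in `inst/extdata/`).
3. `03_adomain_substrates.R` — substrate predictions and pairwise
   signature identities for the synthetase modules.
4. `04_elucidation_benchmark.R` — structure recovery from noiseless and
   noisy simulated spectra, plus MGF benchmark fixtures.

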