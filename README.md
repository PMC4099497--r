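# minibar

Design, authentication and species delimitation with mitochondrial DNA
mini-barcodes.

## The problem

DNA in old museum skins, feathers and sub-fossil bone is fragmented to a few
tens of base pairs — typical degraded extracts have median fragment lengths
near 50 bp, with almost nothing left above ~100 bp. Conventional DNA barcodes
(COI ~650 bp) are unamplifiable from such material, and even modest ~140 bp
amplicons routinely fail, because PCR needs single template molecules that
span *both* primer sites. **Mini-barcodes** solve this: very short (< 100 bp)
hypervariable loci flanked by deeply conserved primer sites, short enough to
amplify from heavily degraded extracts yet variable enough to resolve
species.

`minibar` implements the full computational workflow around such loci, for
anyone identifying degraded specimens against a reference panel:

1. **Discovery** — scan an aligned reference panel for windows whose core
   mean pairwise identity is low (hypervariable) while the pooled identity
   of the two flanks is high (primer sites), and derive degenerate IUPAC
   consensus primers with Wallace-rule melting temperatures.
2. **Resolution scoring** — for each design, count the species whose
   gap-stripped core haplotype is shared with no other species in the panel.
3. **Amplifiability** — fit a left-truncated lognormal to observed fragment
   lengths and predict the probability that an amplicon of length `a`
   amplifies. The default "spanning" weighting is
   `E[max(0, L − a + 1)] / E[L]`, the probability that a random template
   position lies on a fragment covering the whole amplicon.
4. **Authentication** — assemble replicate reads (independent
   amplifications × both sequencing directions) into a consensus that is
   *authenticated* only when every oriented read is identical, the standard
   ancient-DNA defence against damage-induced artefacts.
5. **Identification and delimitation** — rank references by pairwise
   identity, build neighbor-joining trees on Jukes–Cantor distances
   (`d = −(3/4)·ln(1 − 4p/3)`) with bootstrap support and midpoint or
   outgroup rooting, and test species status with one-sided one-sample
   t-tests: is the query's distance to its nearest relative significantly
   greater than within-species distances (`t = (x̄ − μ)/(s/√n)`, alternative
   "less"), yet compatible with congeneric distances? The verdict is
   `distinct_species_supported` when the first test rejects and the second
   does not.
6. **Simulation** — a generator that emulates the whole regime (two-rate
   site model on a genus/species/individual tree, within-species ≈ 0.01 and
   congeneric ≈ 0.09 substitutions/site, 51 bp-median fragment profiles,
   3 × 2 replicate schemes with C→T damage), so every step is testable
   end-to-end with no downloads.

## Worked example

```r
library(minibar)

# a synthetic 12S-like panel: 4 genera x 3 species x 2 individuals
sim <- simulate_panel(panel_sim_spec(n_genera = 4, species_per_genus = 3, seed = 11))
designs <- scan_windows(sim$panel)
designs[[1]]
#> barcode_design 'mb1': flank[50,70) core[70,125) flank[125,145)  core id 0.528, flank id 0.950
evaluate_designs(sim$panel, designs[1:3])
#> evaluation_report (3 designs)
#>   name core_length_bp core_identity flank_identity unique_species_count n_species
#> 1  mb1             55        0.5279         0.9500                   12        12
#> 2  mb2             59        0.5305         0.9531                   12        12
#> 3  mb3             68        0.5412         0.9670                   12        12
#> mean core length: 60.7 bp; mean unique species: 12.0 of 12
```

Every design resolves all 12 species; cores are far more variable (53%
identity) than their primer flanks (95–97%).

```r
# a degraded extract with 51 bp median fragments: which amplicons still work?
prof <- lognormal_profile(51)
amplifiable_fraction(prof, c(64, 84, 138))
#> 0.0751 0.0200 0.000529
```

A 138 bp amplicon is ~140× less amplifiable than a 64 bp one — short
mini-barcodes amplify where conventional targets fail.

```r
# an unknown specimen, amplified 3x per sample and read in both directions
ex <- simulate_query_experiment(sim, profile = lognormal_profile(400, sdlog = 0.1),
                                query_divergence = 0.09, seed = 12)
assemble_replicates(ex$replicate_sets[[1]])
#> consensus_barcode sample1 / planted1: 6 reads, AUTHENTICATED, 0 conflict(s)

head(rank_references(ex$truth$query_sequence, sim$panel), 3)
#>    label   genus species identity
#> 1 SYN001 Genus01    sp01    0.924
#> 2 SYN002 Genus01    sp01    0.924
#> 3 SYN003 Genus01    sp02    0.900

gd <- grouped_distances(panel_distance_matrix(sim$panel), panel_taxonomy(sim$panel))
qd <- jc69_distance(p_distance(ex$truth$query_sequence, sim$panel$records$sequence[1]))
delimit_query(qd, gd$within_species, gd$congeneric)
#> delimitation at alpha = 0.05: distinct_species_supported
#>   query distance: 0.08013 subs/site
#>   vs within-species: one-sample t (less): t(11) = -37.708, p = 2.76e-13  [mean 0.01026, sd 0.006419, n 12, mu 0.08013]
#>   vs congeneric:     one-sample t (less): t(11) = 0.463, p = 0.674  [mean 0.08595, sd 0.04351, n 12, mu 0.08013]
```

The query is vastly more divergent than any conspecific pair (p ≈ 3e-13)
but sits squarely inside the congeneric distance distribution (p = 0.67):
a distinct species in the same genus as its top hit.

## Command line

A thin `minibar` script (installed to the package `exec/` directory) wraps
the same functions:

```sh
minibar design panel.fasta --core-len 50:80 --flank-len 20 \
        --min-flank-id 0.95 --max-core-id 0.80 -o designs.tsv
minibar eval panel.fasta --designs designs.tsv
minibar consensus reads.fasta --mode strict
minibar frag predict --median 51 --amplicon-len 64,84,138
minibar identify panel.fasta --query query.fasta
minibar delimit --query-distance 0.11 --within w.txt --congeneric c.txt
```

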