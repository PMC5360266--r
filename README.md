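# isopick

Selecting one protein isoform per genomic locus before phylogenetic
reconstruction.

Alternative splicing makes most eukaryotic genes produce several protein
isoforms. Similarity searches collect all of them, yet a phylogenetic dataset
needs exactly one sequence per locus: the extras carry redundant signal and
pepper the alignment with gaps that bias trimming and tree inference. Keeping
the longest isoform — the usual shortcut — routinely picks sequences that
align badly. `isopick` is for people assembling protein gene-family datasets
(phylogenomics pipelines, orthology curation) who want that choice made by an
alignment-robustness criterion instead.

## The score

A reference alignment *a* (length ℓ) of the *m* input sequences is compared
with *n* perturbed alignments, each a realignment under a guide tree built by
BioNJ from a bootstrap resample of *a*'s columns. For residue *k* of sequence
*i*, p<sub>ijk</sub> = 1 iff sequence *j*'s residue facing (*i*, *k*) is the
same residue in the reference and the perturbed alignment. With m<sub>k</sub>
residues in the reference column,

    R_ik(b) = (1 / (m_k − 1)) · Σ_{j≠i} p_ijk        (1 if m_k = 1)
    R_ik    = mean over the n replicates
    S_i     = (1 / l_i) · Σ_k R_ik                    so 0 ≤ S_i ≤ 1

and the isoform with the highest S<sub>i</sub> is kept at each locus.
Variants: `gap` divides each p<sub>ijk</sub> by the column's gap count and
penalizes residues facing only gaps (−1/m<sub>g</sub>); `short` divides the
score sum by ℓ instead of l<sub>i</sub>; `ds` skips the bootstrap and scores
each sequence by its mean modified *p*-distance (gap = 21st state) to the
single-isoform backbone, smallest wins; `auto` picks a variant from the
reference alignment's gap structure and size. Distances for the replicate
guide trees can use Poisson (± Gamma), Kimura's PAM approximation, a
Gamma-Poisson JTT approximation (default), or pairwise maximum likelihood
under PAM/JTT/WAG/LG/BLOSUM62.

## Worked example

```r
library(isopick)

# a synthetic 6-species family with known canonical isoforms
fam <- simulate_family(n_species = 6, seq_length = 80, isoform_rate = 0.5,
                       seed = 42)
fam
#> synthetic_family: 6 genes, 9 sequences, 3 alternative isoforms (seed 42 )

fit <- select_isoforms(fam$seqs, variant = "default", n = 10,
                       aligner = aligner_spec("mock"), seed = 1)
summary(fit)
#> Isoform selection summary
#>   variant: default (10 replicates)
#>   sequences: 9  loci: 6
#>   score range: 0.990161 - 1.000000
#>   multi-isoform loci:
#>    gene      id     score selected
#>  g_sp03 sp03_t1 1.0000000     TRUE
#>  g_sp03 sp03_t2 1.0000000    FALSE
#>  g_sp03 sp03_t3 0.9903125    FALSE
#>  g_sp05 sp05_t1 0.9923750     TRUE
#>  g_sp05 sp05_t2 0.9901613    FALSE

sum(fit$selection[names(fam$truth)] == fam$truth)
#> [1] 6        # all six canonical isoforms recovered
```

Scores are agreement proportions: `sp03_t3` (an altered isoform) loses ~1% of
its residue pairings when the guide tree is perturbed, while the canonical
`sp03_t1` stays at 1.0 (the `sp03_t1`/`sp03_t2` tie is resolved to the
lexicographically smallest id, with a warning). `write_outputs(fit, "out")`
writes the reference alignment (`out.aln`), the score table (`out.scores`,
tab-separated, 6 decimals; `out.DistanceScore` in DS mode) and the filtered
FASTA (`out_filtered.fasta`, one record per locus).

The same run from a shell:

```sh
inst/scripts/isoform-select input.fasta --locus-tags isoforms_locus_tag.txt \
    --aligner mafft -n 30 --seed 1 --out output
```

The locus-tag file has two whitespace-separated columns — sequence id
(leading `>` tolerated) and gene id; sequences not listed are treated as
single-isoform loci and always kept.

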