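# mirnascore

Reliability scoring and false-positive characterization for miRNA
microarray data.

## The problem

miRNA microarrays measure relative probe intensities. Normalization makes a
miRNA comparable across samples, but different miRNAs are still not
comparable within a sample: probe affinities differ so much that arrays
routinely assign high values to miRNAs that sequencing of the same material
shows are not expressed at all. Anyone ranking miRNAs from an array profile
— to pick validation candidates, or to flag low-confidence rows before
differential-expression analysis — inherits that false-positive burden.

`mirnascore` is for analysts holding a normalized (e.g. RMA) miRNA
expression table who want each mature miRNA tagged with a reliability score
in [0, 1].

## The model

For each mature miRNA three values are computed: the median expression *m*
across samples, the chronological miRBase accession number *N* (the integer
suffix of `MIMATxxxxxxx`; sequencing-confirmed miRNAs concentrate at low
*N*), and the Spearman correlation *c* between mature and precursor
(pre-miRNA) expression profiles (biogenesis couples the two, so
co-variation is evidence the probe tracks a real transcript). Each is
scaled to [0, 1],

    A = m / m_max,   B = 1 − N / N_max,   C = (c + 1) / 2,

with maxima over the analyzed set, and combined as

    score = 0.5·A + 0.3·B + 0.2·C,

weights chosen to maximize specificity against paired sequencing data and
re-derivable on your own data with `optimize_weights()`. The score lies in
[0, 1]; higher means more credible.

## Worked example

Everything below runs offline on a synthetic paired array/sequencing
dataset with planted ground truth (50 truly expressed + 150 false-positive
miRNAs over 30 samples):

```r
library(mirnascore)

ds  <- generate_synthetic_dataset(synthetic_config(seed = 42))
tab <- score_all(ds$mirna_matrix, ds$precursor_matrix, ds$annotation)
head(tab, 5)
#>              name median mimat correlation      A      B      C  score
#> 1 sim-miR-0045-5p  12.96  1015      0.7677 0.9896 0.9710 0.8839 0.9629
#> 2 sim-miR-0025-5p  12.52   299      0.8340 0.9560 0.9915 0.9170 0.9588
#> 3 sim-miR-0036-5p  12.64   727      0.7784 0.9647 0.9792 0.8892 0.9540
#> 4 sim-miR-0030-5p  12.48   982      0.8131 0.9525 0.9719 0.9066 0.9491
#> 5 sim-miR-0031-5p  12.07  1540      0.8229 0.9209 0.9560 0.9115 0.9296
```

The top rows are high-median, low-MIMAT, precursor-correlated miRNAs —
exactly the profile of a genuinely expressed species. Validating against
the (here simulated) sequencing reference:

```r
concordance(tab, ds$reference)
#> Concordance with sequencing reference
#>   score > 0.75: 46 miRNAs selected
#>   of these, RPM > 10: 33 (discordant: 13)
#>   raw-expression baseline discordant: 37
#>   specificity ratio (baseline/score discordant): 2.846
```

Of the 46 miRNAs the score calls reliable, 33 are confirmed as expressed by
sequencing; selecting the same number of miRNAs by raw median expression
instead lets in 37 unconfirmed ones, i.e. scoring cuts the discordant
selections by a factor of 2.8 here. Sensitivity, as rank separation between
sequencing-confirmed miRNAs and the rest:

```r
sep <- rank_separation(tab$score[ds$reference[tab$name] > 10],
                       tab$score[ds$reference[tab$name] <= 10])
#> confirmed group: mean 0.80 sd 0.08 | unconfirmed: mean 0.59 sd 0.11 | p = 1.47e-20
```

Sequence features of false positives (GC-content, mismatch-tolerant genomic
occurrence counts) are available through `identify_false_positives()`,
`gc_content()`, `count_genomic_occurrences()` and `compare_feature()`.

## Command line

The same pipeline is exposed as subcommands (`exec/mirnascore`, a thin
Rscript over the package functions):

```sh
mirnascore simulate --seed 42 --out-dir fixture
mirnascore score    --mirna fixture/mirna_expression.tsv \
                    --precursor fixture/precursor_expression.tsv \
                    --aliases fixture/aliases.txt \
                    --mapping fixture/precursor_to_mature.tsv \
                    --out scores.tsv
mirnascore validate --scores scores.tsv --reference fixture/reference_rpm.tsv \
                    --out report.tsv
mirnascore fp-profile --mirna fixture/mirna_expression.tsv \
                      --reference fixture/reference_rpm.tsv \
                      --fasta fixture/mature.fa --genome fixture/genome.fa \
                      --out features.tsv
```

All randomness flows from `--seed`; repeated runs are byte-identical.

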