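# REcountR

PCR-free counting of restriction-enzyme-liberated DNA barcodes, and the
analytics built on those counts: pool accuracy/precision statistics,
re-pooling calculations, orthogonal-enzyme multiplexing reports, sequencer
size-bias profiling from paired size standards and normalization barcodes,
per-construct quality summaries, and ATAC-style nucleosomal binning of
paired-end insert sizes.

## The problem and the method

Quantifying a pool of engineered constructs (plasmids, guide libraries,
spike-in standards) by PCR amplicon sequencing inherits the amplification
bias of PCR: template-specific efficiency differences skew the counts, and
the skew grows with cycle number. The alternative implemented here counts
templates directly: each construct carries a unique 20-bp barcode flanked
by full Illumina adapters and type IIS restriction sites, so a digest
releases a sequencing-ready cassette with no amplification step, and read
counts are an unbiased census of template molecules.

Reads are assigned by comparing their first 20 bases against the barcode
panel by Hamming distance, accepting the unique best match within 2
mismatches; ties and budget violations are refused, never guessed. A panel
with minimum pairwise distance `d` is assignment-safe at mismatch budget
`m` iff `d >= 2m + 1`. From assigned counts the package computes relative
abundances `p_i`, replicate precision (per-barcode CV, sample SD over
mean), accuracy (RMSD from a design composition), Pearson correlation
across measurement methods, and corrective re-pooling volumes
`v_i ∝ t_i / p_i`.

For size-bias profiling, each of 30 constructs pairs a variable-length
cassette (molecule lengths 150–1500 bp) with a constant-length (164 bp)
normalization cassette on the same plasmid. The count ratio
`E_i = S_i / N_i` cancels pooling error exactly and isolates the
sequencer's length-dependent clustering efficiency; profiles are reported
relative to their median and compared across runs, platforms and
treatments.

A seeded simulator generates every input the analyses consume — barcode
pools with substitution error, per-template PCR bias `p_i (1+e_i)^c`,
length-dependent clustering weights `w(L) = 2^(-(L-150)/h)`, and paired-end
SAM files — so the full pipeline is testable without any sequencing data.

## Worked example

```r
library(REcountR)

# an even 20-barcode pool, sequenced to 100k reads with 0.5% error
ref <- random_reference(20, seed = 1)
simulate_pool_reads(ref, depth = 100000, error_rate = 0.005, seed = 2,
                    fastq = "even_pool.fastq.gz")

tab <- count_fastq("even_pool.fastq.gz", ref, max_mismatches = 2,
                   sample_id = "even_pool")
tab
#> count_table 'even_pool': 100000 reads, 99988 assigned over 20 barcodes;
#> unassigned distance/ambiguous/short = 12/0/0

ab <- to_abundances(tab)
range(ab$p)                                      # 0.0490 0.0514
rmsd_from_expected(ab, even_composition(names(ab$p)))   # 0.000649
```

All 20 barcodes are recovered close to the designed 5%: the 12 refused
reads are those that accumulated 3+ substitutions in the barcode prefix,
and the RMSD of 6.5e-4 is pure multinomial noise. Three simulated
replicates give `replicate_cv(...)$average_cv` of 0.0115 — counting noise
plus the simulated error, with no amplification bias to add to it.

```r
# size-bias profiling at 1M reads under the default clustering weight
gen <- generate_size_standard_design(seed = 3)
counts <- simulate_clustered_counts(gen$design, depth = 1e6, seed = 4)
prof <- size_bias_profile(counts, gen$design)
head(prof$points[, c("standard_name", "molecule_length", "S", "N", "E")], 2)
#>   standard_name molecule_length     S     N        E
#> 1      16S_0150             150 24402 23616 1.033282
#> 2    GAPDH_0150             150 24328 23771 1.023432
tail(prof$points[, c("standard_name", "molecule_length", "S", "N", "E")], 1)
#>    standard_name molecule_length    S     N         E
#> 30 Tubulin_1500            1500 2415 23523 0.1026655
```

The efficiency falls from ~1.03 at 150 bp to ~0.10 at 1500 bp — the
simulated half-length of 400 bp predicts
`w(150)/w(164) = 1.025` and `w(1500)/w(164) = 0.099`, both recovered
within counting noise despite every plasmid's copy number being drawn
independently.

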