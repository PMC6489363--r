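---
title: "PCR-free barcode counting and sequencer size-bias profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCR-free barcode counting and sequencer size-bias profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(REcountR)
```

## The measurement model

Pooled collections of engineered constructs — plasmid pools, guide or
barcode libraries, synthetic spike-in standards — are usually quantified by
PCR-amplifying a tag and sequencing the amplicon. Amplification efficiency
differs between templates in sequence-dependent, unpredictable ways, so the
read counts drift away from the true template proportions, and the drift
grows with cycle number. The alternative implemented here counts templates
with **no PCR in the measurement path**: each construct carries a unique
20-bp DNA barcode flanked by full Illumina adapters and type IIS
restriction sites (MlyI by default), so a simple digest liberates a
sequencing-ready cassette whose read count is a direct, amplification-free
census of the template molecules.

On the analysis side the model is deliberately minimal. The first
`barcode_length` bases of each read (20 by default — the cassette is read
directly off the adapter, so the barcode starts at base 1) are compared
against every reference barcode by Hamming distance, and the read is
assigned to the unique barcode with minimal distance at most
`max_mismatches` (2 by default). Everything else is a refusal, not a
guess:

* a minimal distance above the budget → `unassigned_distance`;
* two or more barcodes tied at the minimal distance →
  `unassigned_ambiguous` — splitting or first-match assignment would bias
  counts toward reference order, refusing is the only neutral choice;
* a read shorter than the barcode → `unassigned_short`.

Any non-ACGT base in the prefix (including `N`) counts as a mismatch at
that position; no quality filtering or trimming precedes assignment — the
mismatch budget *is* the error tolerance. Only the forward prefix is
scanned, because the cassette design sequences the barcode directly from
the adapter; reverse-complement scanning would only add ambiguity.

Every count table satisfies exact conservation: assigned plus the three
unassigned categories equals the number of input reads. This invariant is
asserted on construction, not merely tested.

### When is assignment unambiguous?

A reference panel is *assignment-safe* at mismatch budget $m$ when every
pair of barcodes is at Hamming distance $\ge 2m + 1$; then no read can sit
within $m$ of two barcodes and ties are impossible by construction.
`check_assignment_safety()` verifies the bound and lists every offending
pair. The panels generated by `random_reference()` guarantee a minimum
pairwise distance of 5 — safe at the default two-mismatch budget.

## Pool statistics

`to_abundances()` converts assigned counts to relative abundances
$p_i = c_i / \sum_j c_j$. On top of these:

* **Precision** — `replicate_cv()`: per-barcode coefficient of variation
  across replicate measurements, using the sample ($n-1$) standard
  deviation because replicate counts are small (typically 3), and the
  unweighted mean across barcodes as the summary. At depth $10^6$ over an
  even 20-barcode pool, multinomial counting noise alone gives an average
  CV of $\sqrt{(1-p)/(np)} \approx 0.0044$ — measurement platforms add
  variance on top of this floor.
* **Accuracy** — `rmsd_from_expected()`: root mean squared deviation of the
  measured composition from the design targets (e.g. 5% per construct for
  an even 20-plasmid pool).
* **Cross-method agreement** — `correlation_matrix()`: Pearson correlation
  between labelled abundance vectors (e.g. PCR-free counts vs droplet
  digital PCR vs amplicon measurements at various cycle numbers). Fractions
  are correlated by default; a `log10` flag covers the case where relative
  error is the quantity of interest. The choice matters for staggered
  pools, and neither convention is canonical.
* **Re-pooling** — `repooling_volumes()`: assuming equal stock
  concentrations (stocks are normalized before pooling), the corrective
  volume is $v_i \propto t_i / p_i$, scaled to the requested total. If the
  measurement equals the target this is a fixed point (uniform volumes);
  otherwise a second measurement of the re-mixed pool has strictly smaller
  RMSD in expectation, which the test suite verifies by simulation.
* **Orthogonal-enzyme multiplexing** — `enzyme_group_report()`: when
  construct groups are flanked by different enzymes' sites, a digest with
  one enzyme should release only its own group. The report partitions
  mapped reads by the reference's `enzyme_group` labels and computes the
  on-/off-target fractions over mapped reads (the unassigned categories say
  nothing about digest specificity).

## Size-bias profiling

Illumina instruments cluster short library molecules more efficiently than
long ones, with magnitude and shape differing between instrument models,
runs, and even denaturation treatments. The size-standard design measures
this directly: each of 30 constructs (10 nested insert lengths per backbone
× 3 backbone molecules, labelled 16S/Tubulin/GAPDH) carries a
variable-length cassette — adapter-flanked molecule lengths spanning
150–1500 bp, i.e. inserts of 22–1372 bp around a constant 128-bp adapter
flank — plus a constant-length (164 bp) normalization cassette on the same
plasmid.

Because the two cassettes on one plasmid are exactly equimolar, the count
ratio

$$E_i = S_i / N_i$$

cancels any error in pooling the 30 plasmids and isolates the length
effect. `size_bias_profile()` reports $E_i$ together with
$\tilde E_i = E_i / \mathrm{median}_j(E_j)$. The median scale was chosen
over the mean or an anchor point because it is robust to depletion of a
single length class (the freeze–thaw effect concentrates at 150 bp), and
over "fraction of total standard reads" because it keeps $\tilde E_i$
interpretable as a relative clustering efficiency. Points whose
normalization count falls below `min_norm_count` (default 100) are excluded
with a recorded reason rather than contributing unstable ratios.

`compare_profiles()` aligns profiles on their shared retained standards and
reports per-length ratios $R_i = \tilde E_i^A / \tilde E_i^B$ (first pair)
and per-length CV across all runs. The divergence summary is

$$\texttt{max\_fold\_difference} = \max_i R_i \,/\, \min_i R_i,$$

the spread of the between-run ratio across the shared length range. This
quantity is independent of each profile's normalization constant, so it
compares curve *shapes*; a per-length fold $\max(R_i, 1/R_i)$ would change
with the normalization convention. Under the default simulator, two
platforms with clustering half-lengths 400 bp and 150 bp diverge by
$2^{(L-150)(1/150-1/400)}$ relative to the 150-bp point — a factor of about
21 by 1200 bp — and the acceptance suite checks the measured divergence
against this closed form.

The backbone label travels with every profile point so construct-specific
divergence (observed on one platform for a structured 16S backbone) can be
examined as a per-backbone split; no secondary-structure modelling is
attempted.

## Per-construct quality profiling

`per_construct_quality()` splits reads by barcode, trims every assigned
read to `trim_length` bases (50 by default) so constructs and runs are
comparable, and reports the mean Phred score over all bases of all trimmed
reads for each construct with at least `min_reads` (100) assigned reads.
Reads shorter than the trim length contribute no bases and are tallied.
Averaging is done in Phred units by default — the common convention for
per-construct summaries; `prob_domain = TRUE` averages error probabilities
instead and converts back, which weights poor bases more heavily. The
original convention for this analysis is not documented anywhere, so both
are provided and the default is stated rather than implied.

## ATAC-style fragment binning

For paired-end chromatin accessibility data, the insert-size distribution
carries the biology: fragments under 100 bp are sub-nucleosomal, and the
canonical nucleosomal classes are 180–247 (mono), 315–473 (di) and 558–615
bp (tri). `classify_insert()` implements exactly these inclusive integer
ranges; the gaps between them (100–179, 248–314, 474–557, > 615) form an
explicit `unbinned` class rather than being merged into a neighbour,
because downstream analyses that split files by bin necessarily leave gap
reads out.

Cross-sample comparisons require a fixed depth, so
`subsample_alignments()` draws `depth / 2` templates uniformly without
replacement — both mates kept or dropped together, header and surviving
records preserved byte-for-byte — deterministically for a given seed. The
original tooling for this step published no sampling scheme or seed policy,
so determinism-given-seed is this package's contract, and every stochastic
entry point requires an explicit seed. `bin_proportions()` takes one insert
size per template from the mate bearing the positive template-length field;
pairs with no positive length or with mates on different contigs are
counted as `undefined_templates`, never guessed. Duplicate and
mitochondrial filtering are assumed done upstream by standard tools.

## The simulator and what it does (not) emulate

The `simdata` functions generate every input the analyses consume, so the
whole package is testable from code alone:

* `simulate_pool_reads()` — multinomial (or exact largest-remainder)
  barcode identities at chosen proportions, reads built as barcode +
  constant tail, i.i.d. substitution errors at rate $\varepsilon \le 0.1$
  (each erroneous base becomes one of the three other bases uniformly),
  constant or per-position Phred qualities. Substitution-only by design:
  the cassette is read from the adapter at a fixed offset, so indels are
  outside the measurement model.
* `simulate_pcr_bias()` — per-template efficiency $e_i \in (0,1]$ constant
  across cycles, deterministic expectation $p_i(1+e_i)^c$ (renormalized) or
  stochastic per-cycle binomial duplication. The underlying studies report
  only the empirical cycle dependence, not a mechanism; this is the
  simplest model exhibiting it, and with heterogeneous $e_i$ it reproduces
  both the monotone RMSD growth with cycle number and the compression of a
  staggered pool's dynamic range when rare templates amplify faster.
* `simulate_clustered_counts()` — standard barcode $i$ drawn with
  probability $\propto m_i\,w(L_i)$ and its normalization barcode
  $\propto m_i\,w(164)$, where $w(L) = 2^{-(L - L_0)/h}$ by default
  ($L_0 = 150$ bp, half-length $h = 400$ bp) and $m_i$ is an optional
  copy-number perturbation standing in for pooling error. Any tabulated
  $w(L)$ is accepted; published curves are platform-specific and not
  parameterized, so the exponential default is chosen for testability, not
  platform fidelity. The generator's $w$ is the recovery oracle for the
  profiling code.
* `simulate_atac_sam()` — properly paired SAM templates at a weighted
  insert-size mixture.

Every generator is a pure function of its parameters and seed (seeded
locally, so callers' RNG state is untouched), and each offers an
exact-count mode so deterministic tests exist alongside stochastic ones.

What the simulator does **not** emulate: competition between co-loaded
libraries for clustering sites (lane-context effects), polymerase-specific
chimeras, per-cycle quality degradation, or binned quality scores. Passing
tests therefore demonstrate correctness of the counting and profiling
machinery under the stated statistical model — not that any particular
instrument follows the exponential weight, which real profiles measurably
do not across their whole range.

## Numerical and design choices

* **Tie-break:** ambiguous reads are refused, never split (see above).
* **CV convention:** sample standard deviation ($n-1$); unweighted mean
  over barcodes for the average CV.
* **Zero guards:** abundances of a table with zero assigned reads,
  re-pooling with an undetected construct, CV of a zero-mean vector, and
  enzyme reports over zero mapped reads are all explicit errors, never
  silent `NaN`s.
* **Largest-remainder apportionment** breaks remainder ties by index
  order, guaranteeing counts sum exactly to the requested depth.
* **Reference hygiene:** duplicate names, duplicate sequences, wrong
  lengths and non-ACGT characters are hard errors at load; over-long FASTA
  records are truncated to the leading `barcode_length` bases with a
  warning, since only the leading bases are read.
* **Atomic outputs:** every file is written to a temporary name and
  renamed, so failures never leave partial outputs.

## Problem sizes in the test suite

The tests run the full pipeline at depths of $2\times10^3$–$10^5$ reads for
FASTQ-level checks, $10^6$ draws for multinomial-precision and size-bias
recovery checks (direct count simulation, no FASTQ materialization), 10,000
randomized reads for the brute-force assignment equivalence suite, and
5,000-template SAM files for the binning checks — sizes at which the
binomial 3-standard-error bands used throughout are tight enough to detect
real defects while keeping the whole suite under half a minute.

## Limitations

* Assignment is a linear scan over the panel — the design point is tens to
  a few hundred barcodes, not genome-scale tag libraries.
* Abundances are relative; absolute quantification requires a spike-in of
  known concentration, which is out of scope.
* Size-bias profiles are relative clustering efficiencies; comparisons
  across runs sequenced alongside different co-loaded libraries confound
  instrument effects with lane context, which the package documents but
  cannot correct.
* The quality report summarizes whole-read means after trimming; per-cycle
  curves are out of scope.
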