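---
title: "Methods: poly(A) signal discovery and stage-specific APA calling"
author: "apasignal"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: poly(A) signal discovery and stage-specific APA calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`apasignal` implements a complete analysis chain for alternative
polyadenylation (APA) from 3'-end sequencing cleavage-site tables: clustering
of cleavage events into poly(A) site clusters (PACs), removal of
internal-priming artifacts, genomic-region annotation, usage-based site
classification, discovery of over-represented poly(A) signal words against a
first-order Markov background with a self-overlap-corrected variance,
region-wise *cis*-element schemas, and entropy-based calling of
developmental-stage-specific sites across a nine-stage expression matrix
(five embryonic stages and four adult stages, as in a frog developmental
series). A synthetic-data generator with a full truth table closes the loop:
every stage of the pipeline is tested against planted ground truth.

# Coordinate conventions

All flank analysis uses a relative axis around the cleavage site in which
position −1 is the last templated nucleotide and +1 the first downstream
nucleotide; there is no position 0. Flanks cover −300..−1 (upstream, sense
strand, transcribed to RNA) and +1..+100 (downstream). A motif's *position*
is the relative coordinate of its **first** base; "AAUAAA at −23" means the
hexamer occupies −23..−18. Gene models are handled 1-based inclusive (GFF3);
cleavage events are exchanged as 6-column BED (0-based half-open) with the
interval `[p−1, p)` for a cleavage position `p`. Conversions happen only at
the I/O boundary.

# Site processing

Cleavage events on the same chromosome and strand are chained by single
linkage: adjacent events at most `max_gap = 24` nt apart join one cluster.
The representative position is the member with the highest total read count;
ties resolve to the most downstream member in the direction of transcription
(3'-end protocols skew peaks 3'). Internal-priming artifacts are detected in
the sense-strand window +1..+10: a window with six or more adenines
(`fail_ARS`), a leading AAAA/AGAA/AAGA/AAAG tetramer at +1..+4
(`fail_tetramer`), or a run of more than five consecutive adenines
(`fail_runA`) disqualifies the site. The checks run in that order and the
first failing rule is reported; note that any A-run of length ≥ 6 inside a
10-nt window already implies ≥ 6 adenines, so `fail_runA` is reachable only
if the ARS check were disabled — the rule is kept for completeness and for
configurations with a wider window. Sites with less than 10 nt of downstream
contig are kept and flagged as edge cases rather than filtered.

# The Markov background and word statistics

The background model is a first-order Markov chain fitted by maximum
likelihood on the region's own sequences: mononucleotide frequencies
$f_o(a)$ and dinucleotide frequencies $f_o(ab)$, counted within sequences
only. The expected per-position probability of a word $w_1 \dots w_k$ is

$$f_e(w) = \frac{\prod_{i=1}^{k-1} f_o(w_i w_{i+1})}
                {\prod_{i=2}^{k-1} f_o(w_i)},$$

which equals the exact stationary chain probability when the two frequency
families are consistent (`expected_kmer_freq` is tested against brute-force
enumeration over all 4096 hexamers). The expected occurrence count over
sequences of lengths $l_i$ is $O_e = f_e \sum_i (l_i - k + 1)$.

The variance of a word count is **not** binomial: occurrences of
self-overlapping words (AAAAAA has overlap periods 1–5, AAUAAA has periods 4
and 5) are positively correlated, occurrences closer than $k$ at non-period
distances are mutually exclusive, and even non-overlapping occurrences are
weakly correlated through the chain. `kmer_sd` computes the exact
stationary-chain variance with all three terms, using powers of the
transition matrix for the long-range part. The acceptance check for this
quantity is a Monte-Carlo oracle: the analytic SD must match the empirical
SD over 10,000 simulated sequences within three times the Monte-Carlo
standard error, for both overlapping and non-overlapping words under two
backgrounds. The over-representation score is
$z_{oe} = (O_o - O_e)/SD$, and tail probabilities use the upper cumulative
binomial $P(X \ge O_o)$, $X \sim \mathrm{Bin}(T, f_e)$, computed in log
space.

# Greedy signal selection

Within a signal window (the positioning element −34..−13 for 3'UTR sites),
the selection loop repeatedly takes the most frequent hexamer of the current
sequence set (count ties break lexicographically), accepts it when its
binomial p-value is below `p_cut = 1e-5` **and** its positional SD is at
most `sd_cut = 7` nt, then removes every sequence containing the accepted
word within the window (a masking mode that blanks only covered positions is
available). Rejected words are never reconsidered, so between acceptances
the procedure simply walks down the frequency ranking; the implementation
exploits this for speed without changing semantics. Positional statistics
are always computed on the original, unmasked set, because removal inflates
the apparent dispersion of later words.

One numerical design choice deserves emphasis: dispersion is judged on the
selection window *expanded by 9 nt on each side* (`pos_margin`). Inside a
~20-nt window the positional SD of even a uniformly scattered word cannot
exceed ~6 nt, so a cutoff of 7 would never fire; on the ~40-nt expanded
window a positionally coherent signal keeps its true spread (background
occurrences remain rare) while a scattered word shows SD ≈ 11 and is
rejected. The margin is configurable.

# Strong-vs-weak screening and schemas

Sites are classified per gene by pooled read share: a single site is
`unique`; a share strictly above 0.7 makes a site `strong` and its siblings
`weak`; multi-site genes without a strong site are `universal`. Control
pseudo-sites are placed at genomic AAUAAA occurrences with no real site
within 50 nt, positioned so the hexamer starts at relative −23 of the
control, mirroring the observed signal position.

The usage-coupled screen combines two scores per word: $z_{oe}$ must exceed
the region's empirical 99th-percentile (the distribution-based p < 0.01
rule) and the two-proportion z between the strong and weak sets,
$z_{sw} = (O_s/N_s - O_w/N_w)/\sqrt{p(1-p)(1/N_s + 1/N_w)}$ with pooled
$p = (O_s+O_w)/(N_s+N_w)$, must reach 1.96. A literal variant that places
raw count differences over the proportion-scale standard error is retained
behind `printed_form = TRUE` for comparison, but the proportion form is the
one whose null calibration is verified (type-I error 0.05 ± 0.01 at
|z| > 1.96 in simulation). Because the percentile rule always admits the top
1% of words, small inputs select background noise alongside true signals;
this mirrors the screen's definition, and the clustering step then separates
the planted families from noise groups.

Selected hexamers are grouped by average-linkage hierarchical clustering of
a shift-penalised mismatch distance: $d(a,b) = \min_s(\text{mismatches in
overlap} + 0.5|s|)$ over shifts $|s| \le 3$, cut at height 2.6. Each group
is aligned at the distance-minimising shifts against its medoid; the
position frequency matrix counts bases per column (columns covered by every
member sum to the group size) and the consensus takes per-column majority
bases with IUPAC codes for ties. This replaces generic progressive
alignment, which is overkill for fixed-length hexamers and irreproducible
across aligner versions.

The window tables per genomic class are fixed constants of the region
models: 3'UTR uses USE −100..−35, PE −34..−13, CEL −12..−3, CER +1..+33,
DSE +34..+100 (the cleavage dinucleotide −2,−1 is deliberately uncovered);
5'UTR uses USE −100..−40, PE −40..−10, CE −10..+10, DSE +10..+100; CDS uses
USE −100..−30, CE −30..+30, DSE +30..+100; introns use USE −100..−40,
PE −40..−10, CEL −10..−1, CER +1..+30, DSE +30..+100. Where printed bounds
share an endpoint the windows are kept verbatim rather than trimmed.

# Region annotation

Sites are assigned strand-specifically with precedence
3'UTR > CDS > 5'UTR > intron across all overlapping transcripts; the
precedence favours mature-mRNA assignments and is asserted to be invariant
to transcript input order. Sites outside every transcript but within 1,000
nt downstream of a same-strand gene 3' end are `Ex_3UTR` (with distance
recorded); the symmetric rule upstream of 5' ends gives `Ex_5UTR`; all else
is intergenic. The 1,000-nt default reflects the observation that about
half of downstream sites fall within 500 nt of an annotated 3' end, so
1,000 captures the bulk while bounding ambiguity; it is configurable.
Gene-level summaries count sites per region, define proximal
(5'UTR+CDS+intron) and distal (3'UTR+Ex_3UTR) frequencies, categorise genes
as non/rare/moderate/abundant APA (0 / 1 / 2–4 / >4 sites), and correlate
APA frequency with gene length, intron count and mean intron length by
pairwise Pearson tests.

# Stage-specificity entropy

Counts are scaled to counts-per-million within each stage before entropy is
computed, so that specificity is not confounded with sequencing depth. For
a site's normalised profile $x$, $H = -\sum p_k \log_2 p_k$ with
$p_k = x_k/\sum x$, and the outlier-adjusted entropy is
$\mathrm{modeH} = H(|x - T_{bw}|)$ where $T_{bw}$ is the one-step Tukey
biweight (tuning constant $c = 5$, scale floor $\varepsilon = 10^{-4}$;
with zero MAD the floor turns every off-median point into an outlier, so
the estimate collapses to the mode). A one-hot profile has
$H = \mathrm{modeH} = 0$; a flat profile has $H = \log_2 9 \approx 3.17$ and
modeH defined as $\log_2 n$ when the residual vector vanishes exactly. Both
statistics are scale-invariant up to a negligible wobble introduced by the
absolute $\varepsilon$ floor.

Specific sites are those in the lowest 5% of **both** H and modeH among
sites with at least 5 total reads; constitutive sites are in the highest 5%
of both (low entropy = concentrated expression, the robust-outlier
convention for tissue-specificity detection; the realised cutoff values are
reported with the labels). Sites below the read floor are labelled
`low_expression` and never called. Because the rule intersects two rankings,
the called sets are typically much smaller than 5% — on a few hundred sites
the constitutive intersection can be empty; at the tested scale of 10,000
sites both labels recover their planted archetypes with purity above 95%.
Note that the two entropy statistics agree on direction here; a reading in
which specific sites sit at *high* entropy contradicts the definition of H
and is not implemented, though both the percentile and the direction are
parameters.

Per-stage summaries assign each specific site to its maximally expressed
stage, count period-expressed sites (any reads at the stage), compute APA
ratios (sites per owning gene) for both sets, compare region compositions
of specific versus constitutive sites, and tabulate pairwise gene overlaps
between stage-specific gene sets.

# The synthetic-data generator

The generator is first-class, tested code and defines the study conditions;
its defaults are not tuned per test. Genes (default 2,500–6,000 nt,
0–5 introns, UTRs of 120–300/250–450 nt) are laid out 50 per chromosome
with 2-kb intergenic spacers on i.i.d. background sequence (uniform
composition by default, per-region overrides available). Every gene gets
one 3'UTR site plus Poisson(1.2) extra sites sampled over regions
(3'UTR/intron/CDS/5'UTR/extended 3'UTR), at least 150 nt apart — the gap
guarantees that planted motifs and downstream filter windows of different
sites cannot collide. Each site receives a YA cleavage dinucleotide at
(−2,−1) with probability 0.8, and grammar motifs per element: by default
AAUAAA (50%) or AUUAAA (20%) starting at −23 ± 4 in the positioning
element, and a GU/U-rich word at +15 ± 5 downstream. Planted offsets,
motifs, artifact flags and per-stage means are recorded in a truth table;
one truth row maps to one main cleavage event plus up to two minor events
within 12 nt carrying a small binomial share of the reads, so clustering is
exercised and cluster totals equal planted totals exactly.

Stage counts are negative binomial (dispersion 0.2) over nine stages with
three archetypes: stage-specific (mean 200 at one stage, 0.2 elsewhere),
constitutive (mean 50 everywhere) and background (mean 20 at 2–6 random
stages), mixed 20/20/60. Constitutive labels are drawn preferentially (85%)
from 3'UTR sites and specific labels preferentially (70%) from proximal
sites, emulating the observed association between specificity and proximal
polyadenylation. Replicates are not simulated; the entropy analysis
operates on stage-level columns.

Internal-priming artifacts rewrite the +1..+10 window of a configurable
fraction of sites using one of the three removal rules chosen uniformly;
conversely, every clean site's window is re-sampled until it passes the
filter (planted motif positions are never touched), so on synthetic data
the filter's recall and precision are exactly 1 by construction — the
closed-loop property the acceptance suite asserts. Two lighter generators
expose the same machinery at smaller scales: `simulate_flanks` plants
grammar motifs (plus an optional uniformly scattered decoy word) directly
into i.i.d. flanks for motif-statistics studies, and
`simulate_stage_counts` emits only the count matrix with labels.

What the generator does **not** emulate: sequencing reads and alignment
error, transcript isoform structure beyond one transcript per gene,
usage-coupled signal strength (signals are planted independently of the
strong/weak class, so the z_sw screen is validated on explicitly
constructed strong/weak sets rather than through the generator), genomic
base composition heterogeneity, and replicate noise within stages. Passing
tests therefore demonstrate correctness of the computations and recovery
under the stated model, not performance on real libraries.

# Problem sizes and determinism

The test and acceptance workloads use 2,000 flanks for signal recovery,
10,000 length-100 sequences per Monte-Carlo SD check, 5,000 null replicates
of the two-proportion screen at 10,000 draws, ~4,900 planted sites (2,300
genes) for the filter closed loop, and 10,000 sites for specificity
recovery; these sizes keep every check's Monte-Carlo error well inside its
tolerance. All generators are deterministic given (config, seed): identical
runs produce byte-identical FASTA/GFF3/BED/TSV outputs, which the pipeline
test asserts. The pipeline writes a JSON manifest with parameters, record
counts per stage and MD5 checksums of every output file.

# Known limitations

Eq-style printed forms of the strong/weak statistic in the source
literature are dimensionally inconsistent; the standard two-proportion form
is primary here (see above). The quantile-based z screen always selects
~1% of words, so schema tables on small site sets contain noise groups
alongside planted families. The Markov background is first-order only;
words longer than 6 are supported by the same machinery but the variance
computation assumes stationarity of the fitted chain. `fail_runA` is
shadowed by `fail_ARS` at the default window, as noted. Extension-region
assignment takes the nearest gene only and does not arbitrate overlapping
extensions of adjacent genes beyond distance.
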