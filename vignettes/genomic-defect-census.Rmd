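---
title: "Methods: a genomic-defect census for small, declining populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a genomic-defect census for small, declining populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Nearly neutral theory predicts that when the effective population size
$N_e$ collapses, mutations with selection coefficients $|s| \lesssim
1/(2N_e)$ stop being purged and accumulate. A pair of diploid genomes from
the same species sequenced before and after a sustained decline — for
example an ancient mainland individual at ~11X coverage and a late island
individual at ~17X — lets this prediction be tested directly by counting
classes of putatively detrimental variants in each genome. `meltdownr`
implements the four detectors such a census needs, a forward simulator for
the theoretical expectation, and a synthetic-data generator that makes the
entire pipeline testable end to end without any external data.

## Coding effects and Hn/Hs

SNPs inside coding sequence are classified against the standard genetic
code as synonymous, non-synonymous, nonsense (premature stop), or
stop-loss; minus-strand genes are handled by complementing the genomic
alternate allele into transcript space. Per-class heterozygosity is

$$H_c = \frac{\text{het sites in class } c}{L_c}, \qquad
  \sigma_c = \sqrt{H_c (1 - H_c) / L_c},$$

with $L_c$ the fractional (Nei–Gojobori 1986 style) site count: each codon
position contributes to $L_{syn}$ the fraction of its three possible
changes that are synonymous, and the complement to $L_{nonsyn}$;
stop-creating changes count as non-synonymous and the terminal stop codon
is excluded. The source material never states its denominators, so this
standard convention is our documented choice, as is the binomial standard
error (the tables it feeds print "± 2σ" without defining σ). A site
observed in several overlapping transcripts is counted once at its most
severe effect (nonsense > non-synonymous > synonymous) to avoid
double-counting in genome-wide $H$.

Two systematic corrections matter at low coverage:

* **Heterozygote under-calling.** A fraction `fnr` of true heterozygotes
  is missed; corrected totals are `hom + het / (1 - fnr)`. Defaults are
  0.30 for SNP genotypes (established for these libraries by independent
  replication) and 0.005 for deletions (estimated by depth downsampling,
  below).
* **Post-mortem deamination.** Ancient DNA accumulates C→U lesions that
  read as C→T (G→A on the other strand). Any variant whose unordered
  ref/alt pair is {C,T} or {A,G} is flagged, and every summary can be
  recomputed with flagged sites excluded. Both directions of both
  transition pairs are dropped — a deliberately blunt filter that
  sacrifices genuine transitions for robustness.

## Deletions from read depth

Coverage depth is modelled as piecewise constant within 20 kb windows. For
each window the one-mean fit (residual sum of squares $RSS_1$) is compared
with a background-plus-tract fit ($RSS_2$), with tract boundaries on a
100 bp grid and tract length restricted to 1–10 kb (half the window; calls
below 1 kb are never emitted because stochastic coverage makes them
unreliable at 11–17X). The statistic for the best tract is

$$\Lambda = n \,\ln\!\left(RSS_1 / RSS_2\right),$$

referred to $\chi^2_1$ ("one regression line vs. two", one change-point
worth of freedom). "Regression lines" are constant-mean fits here: depth
has no meaningful slope within 20 kb. Masked (reference-N) positions are
excluded from both RSS terms; windows over half masked are skipped.

**Multiple testing.** The per-window best tract is a maximum over all
~13,000 candidate (start, length) placements, so its nominal $\chi^2_1$
p-value is anti-conservative: calibration on negative-binomial null tracks
shows the per-window maximum has median ≈ 8.6 and would exceed a
windows-only Bonferroni threshold several percent of the time, i.e. a
family-wise error near 1 on a null genome. We therefore Bonferroni-correct
over the *total number of candidate placements tested genome-wide*. Each
fixed placement is asymptotically $\chi^2_1$, so the union bound is valid
and the family-wise error is controlled at $\alpha$. Real deletion signals
at these depths carry $\Lambda$ in the hundreds to thousands, far above
either threshold, so sensitivity is unaffected; the test suite verifies
recall ≥ 0.95 on planted 1–10 kb homozygous deletions at 15X together with
the null-genome error bound.

Tracts from adjacent windows that overlap or abut within one grid step are
merged and re-genotyped from pooled depth. Genotyping uses the background
depth (median of unmasked depth around the tract, robust to the tract
itself): a tract is homozygous iff its mean depth is strictly below 10% of
background ("less than 10%" wins over the ambiguous "≤ 10%" phrasing; the
boundary case is genotyped heterozygous), and a call is flagged when at
least half its positions have exactly zero coverage — such "hemizygous"
calls often hide multiple unresolvable homozygous deletions. Intervals
called homozygous in *every* sample (reciprocal overlap ≥ 50%) are
insertions in the reference assembly rather than deletions in the samples
and are removed everywhere. The deletion false-negative rate at lower
coverage is estimated by binomially thinning the depth track (per-base
thinning with $p = d_{target}/d_{current}$; read-level thinning is not
available from a depth track) and re-running the caller.

## Retrogenes

A retrogene (processed pseudogene) is an intron-less gene copy; in genomic
reads it betrays itself by fragments that span exon–exon junctions
contiguously. A read aligned to a transcript is a junction read when its
aligned span covers at least 10 bp on *each* side of a junction —
soft-clipped bases do not count, which automatically rejects genomic reads
that run off an exon end. Junction reads that align equally well or better
somewhere in the genome (by the `AS` alignment-score tag; ties discard,
the maximum over multiple genomic hits is used) are explained by the
ordinary locus and dropped. A gene is called when the surviving reads
support ≥ 2 distinct junctions with ≥ 3 distinct reads; a read spanning two
junctions supports both but counts once toward the read total. Both
filters are monotone in their thresholds, which the suite checks.

## Forward simulation under a population trajectory

Neutral and selected site classes evolve as independent biallelic
Wright–Fisher processes ("free recombination" — valid for heterozygosity
summaries; no linkage statistics are computed): deterministic viability
selection with genotype fitnesses $(1,\, 1+hs,\, 1+s)$, symmetric recurrent
mutation at rate $\mu$, then binomial drift over $2N$ gametes. Defaults
suit elephantid-scale ancient genomes: $\mu = 3.8\times10^{-8}$, gamma DFE
with mean $-0.043$ and shape $0.23$ (human-estimated), $h = 0.5$, 460
replicates × 100 sites per class, burn-in 100,000 generations. Population
rescaling by $Q$ maps $N \to N/Q$, $t \to t/Q$, $\mu \to \mu Q$,
$s \to sQ$; a floor of $10N$ rescaled burn-in generations is enforced, and
$\mu Q \ge 0.1$ is rejected. Rescaled DFE draws below $-1$ are treated as
lethal (clamped; such sites contribute $\approx 2\mu/(h|s|)$ to $H$
regardless, so the clamp is inconsequential), while a *fixed* $s$ with
$|sQ| \ge 1$ is rejected outright.

Recurrent symmetric mutation replaces the infinite-sites engine of the
original simulations; at these $\mu$ the bias is negligible and the choice
is validated against the exact stationary expectation of the symmetric
two-allele diffusion, $E[H] = \alpha/(2\alpha+1)$ with $\alpha = 4N\mu$
(per-direction rate), against mutation–selection balance
$H \approx 2\mu/(h|s|)$, and against the closed-form neutral decay
$(1 - 1/2N)^t H_0$ across epochs. Initial frequencies start at zero by
default; a `"stationary"` warm start draws the neutral class from
Beta$(4N\mu, 4N\mu)$, which makes large-$N$ decay experiments affordable
without a $10N$ burn-in. Summaries report the ratio of class means (not
the mean of per-replicate ratios) with a percentile bootstrap CI over
replicates. Heterozygosity can be time-averaged over a sampling window at
the end of the run; at equilibrium this trades a longer run for a smaller
Monte-Carlo error (samples 100 generations apart are still correlated on
the $2N$ coalescent time scale, so the effective gain is modest and the
acceptance tolerance of ±0.05 on Hn/Hs budgets for it).

Under the study conditions (ancestral $N_e = 10^4$, $Q = 10$) the
equilibrium ratio computed by `scripts/acceptance.R` is ≈ 0.23, and after
a sustained decline to $N_e = 300$ the ratio rises: the selected-class
heterozygosity is pinned near mutation–selection balance at strongly
selected sites while the neutral denominator decays, the qualitative
signature the census looks for in the data.

## The synthetic corpus

The generator emulates everything the pipeline consumes: a random
reference with non-overlapping multi-exon genes on both strands (every CDS
starts ATG, ends at a stop, translates cleanly), planted SNPs per effect
class chosen by enumerating all single-base codon changes, deletions
≥ 1 kb in het/hom state, intron-less retrocopies emitting junction reads,
and a per-base depth track. Files are written in the standard formats
(FASTA, GFF3, VCF with GT, SAM with AS tags, bedGraph, truth BED/TSV) with
a checksum manifest; a fixed seed reproduces every file byte for byte.
Coordinates are 0-based half-open internally, converted only at format
boundaries.

Deliberate realism choices, and their limits:

* Depth is negative binomial (`size` = dispersion 5 by default — ancient
  libraries are overdispersed; the right value for a given library is
  unknown, so it is a config knob). Heterozygous deletion spans are
  binomial-thinned at 0.5; homozygous spans are zero.
* Damage is applied to *reads only* (C→T and G→A independently at the
  configured rate), never to truth genotypes, so the damage filter can be
  tested as a confounder. Truth SNPs carry the damage *flag* purely as a
  property of their ref/alt pair.
* Alignment scores are `aligned_length − 5 × mismatches`, computed by the
  generator so the retrogene filter has a deterministic comparison key;
  there is no mapping-quality or indel model, and no sequencing error
  beyond damage substitutions.
* Planted deletions keep ≥ 20 kb apart (one caller window). The caller
  allows at most one tract per window, so two deletions sharing a window
  would shadow each other; at census scale (100 deletions in 10 Mb) about
  one collision in ten deletions would otherwise occur by chance and the
  recall measurement would conflate generator geometry with caller
  performance. Real deletions at these densities are effectively this
  sparse.

Passing on this corpus therefore demonstrates coordinate correctness,
classifier agreement, detection power and error control under the stated
noise model — not robustness to mappability artifacts, indels, GC bias, or
alignment errors, none of which are simulated.

## Numerical and scale choices

Problem sizes in the tests and drivers are chosen to exercise every code
path at desk scale: the shared test corpus is 300 kb with 10 genes; the
deletion-recall check uses a 10 Mb genome with 100 planted homozygous
deletions at 15X; the null-calibration uses 40 replicates of 2 Mb; the
equilibrium simulation runs 920–1840 replicates × 100 sites per class
(above the 460-replicate baseline, to shrink the Monte-Carlo error on the
Hn/Hs ratio) with a 10N burn-in and a 4,000-generation sampling window. Ties in the rank-sum
test use the normal approximation with tie correction (checked against
exact enumeration at n ≤ 8); chi-squared tests are Pearson without
continuity correction, with the full 2×2 table reported so any convention
can be audited. The rank-sum statistic is reported in both the
Mann–Whitney U and the rank-sum W conventions, since published values
rarely say which was used. Deletion sharing across samples uses reciprocal
overlap ≥ 50% — no published rule exists, so it is configurable.

## Known limitations

* The change-point model assumes a flat background within 20 kb; real
  coverage waves (GC, mappability) would inflate calls and need masking.
* One tract per window means a second deletion in the same window is
  invisible until it merges across a tile boundary.
* The damage filter removes all transitions, not just damaged ones, so
  damage-excluded counts understate the truth; they are reported alongside
  raw counts, never instead of them.
* The simulator's independent-sites assumption cannot speak to linked
  selection or to LD-based statistics.
* Site-frequency corrections beyond the two heterozygote false-negative
  rates (e.g. reference bias of ancient reads) are out of scope and must
  be handled upstream.
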