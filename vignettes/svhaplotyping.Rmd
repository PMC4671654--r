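---
title: "Multi-evidence SV haplotyping at the NPHP1 locus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-evidence SV haplotyping at the NPHP1 locus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nphp1sv)
```

This vignette is the package's account of its science: the locus model and
its transforms, the error models behind each synthetic evidence type, the
detection and calling procedures, the parameters that matter, and the
design decisions taken where the design was genuinely open.

## The locus model

The human *NPHP1* region (modelled as chr2:110,080,914–111,762,639, about
1.68 Mb) carries two LCR families: three ~45 kb copies (45PROX, 45MID,
45DIST) and two ~358 kb copies (358PROX, 358DIST), with 45PROX embedded in
358PROX and 45DIST in 358DIST. Coordinates in the bundled table follow the
UCSC table convention — the printed start is 0-based, the printed end
1-based — so every interval is half-open and `length = end - start`
(length(45PROX) = 44,372 bp).

A haplotype is represented as an ordered list of *segments* mapping
haplotype coordinates to the reference frame: reference segments carry
`(ref_start, ref_end, strand)`, stuffer segments insert the 5,936 bp
junction sequence that accompanies every 45 kb copy loss. All structural
transforms are segment-list rewrites, so sequence synthesis, fosmid end
projection and in-silico digestion share a single coordinate mapping:

* **Inversion** reverses the segment strictly between 358PROX's end and
  358DIST's start (element order reversed, orientations negated). The true
  breakpoints of the physical event lie somewhere inside the 358 kb
  repeats; placing them exactly at the inner repeat boundaries does not
  change element order or orientation logic, which is all that downstream
  calling uses. Inversion is an involution.
* **Deletion** removes a full 45 kb copy and inserts the stuffer, a net
  change of −(copy length − stuffer length) = −38,436 bp for 45PROX.

The seven known haplotypes are a lookup: H1 (reference), H2 (45PROX loss +
inversion), H3 (inversion), H4 (both losses + inversion), H5 (45PROX
loss), H6 (45DIST loss + inversion), H7 (both losses). `count45` is
conserved as `3 - |lost copies|`.

**NAHR susceptibility** is a purely geometric rule: a haplotype is
susceptible when some pair of 45 kb copies flanks the gene — one proximal,
one distal — with equal orientation signs. No minimum-homology-length term
is included because the geometry alone separates the observed haplotypes;
applying the rule exhaustively gives susceptible = {H1, H2, H3}, protected
= {H4, H5, H6, H7}. For H2 and H3 this classification is an inference from
the geometry (after inversion, 45MID and 45DIST come to flank the gene in
direct orientation); reports carry it like any other call.

## The synthetic-data generator

The generator defines the study conditions; every generator is a pure
function of its inputs and the seed, and leaves the ambient RNG untouched.

**Sequences.** One random master per LCR family is written into every copy
position (the 45 kb master is embedded in the 358 kb master at the offset
the reference implies, so the containments arise automatically); each copy
is then mutated independently at the paralog divergence rate δ (default
0.0025 substitutions/bp, giving pairwise copy identities of ~99.5%, the
magnitude real copies show). Background is uniform i.i.d. sequence — no
repeat or GC model — and divergence is substitution-only; no indels or
gene conversion. SwaI recognition sites (ATTTAAAT, palindromic, so
inversion preserves them) are scrubbed from the assembled sequence and
planted at fixed positions with irregular ~24 ± 8 kb spacing from a
deterministic linear-congruential layout: irregular spacing is what makes
the inversion visible in a fragment list, and planting at absolute
positions gives each copy a distinctive local site pattern. Planted sites
are the only sites, so in-silico digests are fully determined by the
layout.

**Fosmid ESPs.** Clones sample a genotype component (weighted by mixture
fraction), insert length ~ Normal(40 kb, 2.5 kb) truncated positive
(fosmids carry ~40 kb inserts; the library defaults are a modelling
choice), and both ends are projected through the segment map into the
reference frame. Discordance emerges naturally: a clone spanning a lost
copy maps with span enlarged by 38,436 bp, a clone spanning an inversion
breakpoint maps with equal-strand ends, and ends landing in the stuffer
(absent from the reference) are unmappable (mapq 0).

**Rmaps.** A true fragment list is perturbed per molecule: each cut missed
with probability 0.10 (adjacent fragments merge), false cuts as
Poisson(length / 500 kb), multiplicative sizing error Normal(1, 0.05), and
fragments under 800 bp merged into a neighbour (small fragments desorb in
optical mapping). These magnitudes are conventional for the assay and
configurable; the calling results are insensitive to factor-of-two changes
around them.

**aCGH.** The probe design tiles only one copy of each LCR family, so a
probe's signal sums over all homologous copies; per-probe
LR = log2(test dosage × identity factor / reference dosage) +
Normal(0, 0.10). Cross-species divergence is modelled as a single
multiplicative hybridization attenuation (identity factor): at equal copy
number an identity factor of 0.63 yields LR ≈ −0.67, reproducing the
observation that diverged single-copy orthologs sit between 0 and −1.

**Read depth.** 500-bp windows carry the paralog-aggregate diploid copy
number of their reference position (45 kb windows see the genotype's total
45 kb dosage; 358 kb windows the two-copy family dosage; unique windows
the ploidy) plus Normal(0, 0.2) noise — a typical windowed-CN spread at
~25× coverage.

**Populations.** Diploid individuals are independent random unions of
haplotypes. The default frequencies for YRI, CHB+JPT and CEU were chosen
once so that Hardy–Weinberg pairing approximately reproduces the published
diploid CN2..CN6 distributions of those populations (e.g. CN4 most common,
CN6 rare), with the two-copy class dominated by H2 and the three-copy
class by H3 over the minor reference H1.

What passing tests on these simulations do *not* show: robustness to
chimeric clones, reference-assembly gaps, repeat-driven mismapping, indel
divergence between paralogs, or array normalization artifacts — none of
which the generator emulates.

## LCR detection, identity, and motif scanning

`detect_paralogs` finds exact k-mer anchors (k = 31) between the sequence
and itself in both orientations, excluding the trivial diagonal, and
chains anchors on near-constant (anti)diagonals (band 50 bp, maximum gap
2 kb — substitution-only divergence keeps diagonals constant, and at
δ ≤ 1% most 31-mers survive, so planted blocks ≥ 10 kb are recovered with
boundary error ≤ k). Block identity is computed ungapped along the chain
diagonal, which is exact under substitution-only divergence. Blocks
overlapping reciprocally (≥ 50%) are the same physical copy; copies linked
by a pair form a family. One consequence of the embedded architecture: the
45PROX–45DIST match lies on the same anti-diagonal as the 358PROX–358DIST
match and is absorbed into that chain, so the pair list reports the
containing duplication once rather than twice — the family table still
shows all three 45 kb copies.

`pairwise_identity` uses global Needleman–Wunsch with end-gap penalties
(match +1, mismatch −1, gap open 4, gap extend 1 — the exact scoring is a
package choice). Two measures are returned because gap treatment changes
the number: `identity` over match/mismatch columns only, and
`identity_gapped` counting internal gap columns in the denominator.

The PRDM9 hotspot consensus `CCNCCNTNNCCNC` has 8 informative positions.
A position-weight matrix built from this consensus and thresholded at 85%
of its maximum score reduces, under a uniform background, to "at most one
informative mismatch"; that deterministic reduction is what the scanner
implements, on both strands, counting overlapping opposite-strand hits
separately. Counts on real genomic sequence depend on the exact PWM and
background and may differ slightly from this rule.

## Rmap alignment and haplotype calling

The aligner is a global dynamic program over *blocks* pairing a run of
`a` query fragments with `b` reference fragments (`a, b ≤ Δ = 3`):

    cost = (Sq − Sr)² / (2 (σ_rel · Sr)²)  +  c_cut · (a − 1 + b − 1)

with σ_rel = 0.05 and c_cut = 3. The sizing term is the chi-square cost of
the run-sum mismatch under the relative sizing error; the cut term charges
each extra cut discrepancy. In the reported alignment, `cuts_false` counts
extra query cuts (`a > 1` blocks) and `cuts_missed` reference cuts absent
from the query (`b > 1`) — note both describe the same discrepancy seen
from the two maps. The DP is exact (it equals exhaustive enumeration on
all maps up to 6 fragments) and is implemented in C++ for speed.

Consensus construction from single molecules is deliberately simple: the
medoid molecule (minimum total alignment cost to the rest) refined by
averaging 1:1-aligned fragment sizes across molecules. A full iterative
Bayesian map assembly is out of scope; the inference object downstream is
only the consensus-versus-candidate comparison, which this consensus
serves. Calling is model selection: align the consensus to the in-silico
digests of H1–H7 and take the minimum-cost candidate, flagging calls whose
runner-up lies within margin 5.0 of the best cost; the distinct labels
across consensus maps form the allele-type set, and more than two distinct
labels signals mosaicism. With defaults (10 molecules per consensus) the
planted haplotype is recovered in ≥ 95% of seeded replicates for every
candidate.

## Copy-number rules

DLRS is `sd(diff(values)) / sqrt(2)` with the plain sample standard
deviation — vendor implementations use robust spread, but the plain form
is deterministic and testable, which matters more here.

The **intra-species** rule assigns the integer copy number whose
theoretical `log2(c / cn_ref)` is nearest the observed mean (reference
copy number 4, the modal diploid count; ties toward the smaller copy
number; below `log2(0.5 / cn_ref)` — less than half a copy's signal — the
call is 0). Applied to the bundled published aCGH summary it reproduces
the reported copy number for 18 of the 20 human rows and all three gorilla
rows. The two exceptions are structural, not numerical: one cell-line row
at −0.18 was reported as CN3 on the strength of orthogonal optical-map
evidence while another sample at the same −0.18 was reported CN4, and one
patient row at −0.65 (with abnormally high DLRS) was reported CN2 in line
with the known homozygous deletion. No single log-ratio rule can reproduce
both members of either pair, so these rows are asserted as known
discordances rather than targets.

The **inter-species** rule is three-way: absent below −1 (the published
absence boundary), reduced (half the reference) between −1 and −0.25, and
equal above −0.25. The −0.25 boundary is introduced by this package to
separate the gorilla cluster (≥ −0.18, reported equal to human) from the
chimpanzee/orangutan cluster (≤ −0.51, reported reduced); any boundary in
(−0.51, −0.18) reproduces all 14 nonhuman rows, and −0.25 sits near the
middle on the log scale while staying clear of noise around 0.

## Statistics

Kruskal–Wallis (with tie correction, chi-square p-value, and exact
enumeration of group assignments for total n ≤ 10 — enumeration grows
multinomially, and 10 keeps it instantaneous) and Welch's t (with
Welch–Satterthwaite degrees of freedom) are implemented from their
formulas, as the module's contribution, and cross-checked in the tests
against the independent `stats` implementations. Copy-number input to the
population comparison uses integer diploid CN classes.

## Evidence integration

Rmap allele types outrank fosmid classes on conflict — the optical map is
the definitive structural assay, while ESP evidence is a cross-check —
but conflicts are flagged (`fosmid_deletion_discordant`,
`fosmid_inversion_discordant`), never silently dropped. The dosage call
fixes the diploid total 45 kb copy number, and genotype enumeration keeps
every unordered pair of observed allele types whose counts sum to it.
With three or more observed allele types the sample is reported as a
mosaic of two-component mixtures (the observed real-world case); mosaic
fractions are not estimated quantitatively. A functionally haploid sample
(ploidy 1) is reported per-allele without dosage. When three allele types
with loss content {45PROX}, {45DIST + inversion}, {both} meet a dosage of
three, the consistent set is exactly {H5/H7, H6/H7} — the ambiguity is
preserved in the report rather than resolved arbitrarily.

## Numerical and testing choices

Degenerate inputs: empty ESP tables aggregate to no evidence; a site-free
sequence digests to a single fragment; a single-value dosage region has
undefined DLRS (flagged `NA`); zero reference dosage masks a probe;
fragments below the resolution limit merge leftward (rightward at the map
edge).

Problem sizes used by the checks, chosen to make the properties sharp at
interactive runtimes: a 1.68 Mb synthetic reference for detection; 10
molecules per consensus, 100 seeded replicates per haplotype and 200 per
genotype for recovery; 200 clones per fosmid library; 1,000 and 2,000
replicates for the Kruskal–Wallis uniformity and Welch type-I-error
calibrations; exhaustive alignment enumeration up to 6 fragments.

## Known limitations

Breakpoints are modelled at repeat boundaries, not base-pair resolved;
paralog divergence is substitution-only; the aCGH model has no dye bias,
probe QC or normalization step; the Rmap consensus is not a full assembly;
population frequencies are calibrated to published copy-number
distributions, not measured haplotype frequencies; and the inversion
status of deletion haplotypes inferred from geometry (H2/H3 deletion
susceptibility) remains an inference wherever no direct assay bears on it.
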