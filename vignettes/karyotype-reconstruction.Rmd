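---
title: "Reconstructing complex mosaic karyotypes from array and FISH evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing complex mosaic karyotypes from array and FISH evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotracer)
```

## The problem

A genomically unstable cell line carries derivative chromosomes pieced
together from fragments of several chromosomes, some present in only a
fraction of cells. Three evidence streams constrain the reconstruction:

* **SNP arrays** give per-probe total dosage (log R ratio, LRR) and allelic
  dosage (B-allele frequency, BAF) averaged over the cell population;
* **targeted metaphase FISH** localises specific loci and centromeres on
  individual chromosomes, with signal intensity scored in copy-equivalents
  relative to a normal homologue;
* **interphase FISH** counts the fraction of nuclei carrying a locus.

`karyotracer` implements the full chain from a generative karyotype model
through simulation to inference and assembly, so that every inferential
step can be validated against a known truth.

## The dosage model

Each chromosome has two homologues ("a" and "b"); every physical copy
descends from one of them and shares its haplotype — in particular, the two
copies produced by a whole-genome duplication are genotype-identical. For a
segment, clone $c$ (fraction $f_c$, $\sum f_c = 1$) carries $n_{1c}$ copies
of homologue 1 and $n_{2c}$ of homologue 2. A biallelic SNP falls into one
of four founder genotype classes — AA, BB, or heterozygous with the B
allele on either homologue — and its expected BAF is the signal-weighted
mixture

$$\mathrm{BAF} = \frac{\sum_c f_c\, n_{Bc}}{\sum_c f_c\,(n_{1c}+n_{2c})},$$

giving at most four expected *bands* per segment (`baf_band_set()`). LRR is
$\log_2(\max(\varepsilon, \bar N)/2)$ with $\bar N$ the mixture-average
total copy number and $\varepsilon = 0.05$ a floor for zero-copy regions.
The diploid baseline is kept even for near-triploid genomes, matching the
convention of describing karyotypes as gains and losses from diploidy; any
monotone LRR calibration consistent with that reading would serve, and this
is the one the package uses throughout.

Mosaic arithmetic in this model reproduces the characteristic patterns of
a near-triploid mosaic genome: a three-copy region whose single-copy
homologue is lost in one third of cells shows heterozygous bands at
exactly 0.25 and 0.75; a region at 2:6 average homologue dosage under 50%
mosaicism implies $(6-1)/0.5 = 10$ copies of the amplified segment on the
mosaic derivative.

## Simulators

`make_probe_panel()` places probes uniformly (default 30 per Mb, the
density at which a 1 Mb segment carries a comfortable ~30 probes),
excluding centromere intervals where arrays have no probes.
`simulate_array()` adds independent Gaussian noise, default
$\sigma_{BAF} = 0.03$ and $\sigma_{LRR} = 0.15$ — typical post-normalisation
scatter for SNP arrays — truncating BAF to $[0,1]$ rather than redrawing
(real BAF piles up at the rails). With zero noise the track equals the
closed-form expectations exactly, which the tests assert probe-by-probe.

Locus FISH (`simulate_locus_fish()`) counts segment copies fully containing
the probe interval; an overlap of at least 10% but less than 100% yields a
reduced-intensity "(+)" signal, mirroring faint signals at
breakpoint-spanning clones. Tandem copies on one derivative merge into one
multi-copy signal, so four clustered copies render as "++++" rather than
four spots. Interphase FISH is binomial over the clone/sub-mosaic mixture.
Metaphase-to-metaphase signal variability is not modelled: published
intensity scores are averages over many metaphases with no variance given,
so the simulator returns the expectation.

## Inference

**Segmentation** (`segment_tracks()`) is binary changepoint segmentation
jointly on LRR and folded BAF ($|BAF - 0.5|$ of probes in the 0.1–0.9
heterozygous range), each channel standardized by a robust noise estimate
from successive differences. A split must reduce the cost by more than
$6\log n$ — a deliberately conservative BIC-style penalty for a
two-channel mean shift, far below the gain of any 20-probe single-copy
event at default noise. Plain binary segmentation dilutes the gain of a
short interior segment between two long identical flanks, so a windowed
rescue scan additionally tests cutting out the best interior window
(lengths growing geometrically from the minimum segment size, capped at
250 probes) against twice the penalty. Minimum segment size is 20 probes.

**Band extraction** (`extract_baf_bands()`) clusters BAF values by kernel
density peaks (bandwidth 0.015) kept greedily, highest first, subject to a
minimum separation of 0.08 — small enough to separate 0.25 from 0.333, the
closest band pair arising below eight copies; bands of configurations near
the 12-copy ceiling can fall closer than this and then merge with the rail
bands, which is a documented resolution limit. Centers are refined as
cluster means; weights are probe shares.

**Configuration enumeration** (`enumerate_configs()`) scores one-clone
dosages $(n_1, n_2)$ with $n_1 + n_2 \le 12$ (covering a ten-copy amplicon
on top of a two-copy background) and two-clone mixtures over a 0.01
fraction grid. The two clones are constrained to differ by a *single-copy*
gain or loss of one homologue: bands and LRR constrain only the
population-average dosage $(\bar n_1, \bar n_2)$, so any larger jump has a
continuum of aggregate-equivalent representations and is not identifiable
from one segment — the restriction is the parsimony reading (one simple
subclonal event) and makes the reported mosaic fraction well defined.
The score is a weighted SSE between observed and predicted band sets in
both directions (so unmatched predicted bands are penalised and the score
is zero iff bands and LRR match exactly), with homozygous bands
down-weighted (factor 0.2; the 0/1 rails carry no dosage information),
plus $\lambda(\mathrm{LRR}_{pred} - \mathrm{LRR}_{obs})^2$ with
$\lambda = 1$. A two-clone configuration pays an additive parsimony margin
of $10^{-3}$, an order of magnitude above the score residual that
band-center noise can produce but far below the improvement a true mosaic
brings. Ties are broken by fewer clones, then lower mean total copy
number, then lexicographically; scores are quantized at $10^{-8}$ first so
floating-point dust cannot decide a tie, and mirrored clone orderings
collapse to one canonical configuration.

**Mosaic fractions** (`estimate_mosaic_fraction()`) are profiled on the
fraction grid against the observed bands *and* the LRR term — for a
segment that has lost one homologue entirely the bands sit at 0/1 and the
LRR carries all the fraction information. Confidence intervals come from a
200-resample probe bootstrap, seeded.

## Assembly and capture detection

`compose_derivatives()` distributes each called segment's rounded copies
across derivatives in proportion to FISH copy-equivalents; unexplained
copies go to an explicit "unplaced" bucket and FISH excesses produce
structured conflict reports, never silent drops or exceptions. Composition
is multiset-level: array plus locus FISH cannot order segments within a
derivative, so order is reported only where adjacency evidence exists
(for the fixture, the published ordering of the der(20) short arm).

`solve_homologue_assignment()` searches all label assignments of a
chromosome's content pieces (the first piece pinned to kill the global
label swap) for those matching per-segment (major, minor) dosages within
tolerance; a relation such as "these two derivatives carry different
homologues" is reported when *every* optimal assignment agrees on it, even
if absolute labels are not determined.

`detect_centromere_capture()` flags a derivative when every centromere it
carries (i) comes from a chromosome contributing less than 25% of the
derivative's base content, (ii) sits on a fragment confined to that
centromere ± 3 Mb (plus a 250 kb slack absorbing probe-resolution
boundary error), and (iii) the majority chromosome's own centromere is
absent. The confinement condition is what separates capture from ordinary
unbalanced translocation: a translocated centric arm always runs out to a
telomere and is never confined to the pericentromeric window.
`detect_telomere_capture()` flags an end capped by a *short* (≤ 10 Mb)
subtelomeric fragment of a chromosome different from the adjacent
content; without the length cut every translocation derivative would be
"telomere capture", and with it only genuine short caps — like a 5.8 Mb
6q-subtelomere fragment sealing a deleted chromosome 7 — are called.

## The U937 fixture

The encoded cell population is built by applying an explicit event history
to a triploid founder (whole-genome duplication of homologue "a" of every
autosome plus the X, then loss of the Y), which guarantees genotype
sharing between duplicated copies and makes the fixture reproducible
segment-for-segment from its event log. Three clones (nominal fractions
0.30 / 0.50 / 0.20; the karyotyped cell counts 21/71, 37/71, 13/71 are
available as an alternative mode) share a 62-chromosome stemline; the
second clone adds the mosaic 6p-amplified derivative and a 7q deletion,
the third replaces the 7q deletion by an unbalanced 6;7 translocation and
loses one 12 and one 22. The larger of the two overlapping proximal-5q
deletions is encoded as a cross-cutting sub-mosaic event in 30% of cells,
deliberately independent of clone structure because the data do not
resolve which clones carry it — the fixture's choice here is a modelling
convenience, not ground truth. The homologue history of the two normal
chromosomes 20 is likewise left unannotated beyond both carrying the same
haplotype (the observable fact: two-copy LOH at 20q12).

Breakpoint coordinates are placed at band resolution, consistent with the
published FISH probe positions (the targeted BAC panel is encoded with its
GRCh38 coordinates); the 6 Mb pericentromeric chromosome-11 fragment and
the 1.9 Mb 11q24 fragment of the der(11)t(11;16;20) are exact by
construction, the latter inside its published boundary-uncertainty
intervals. For the amplified 6p21.3 segment the arithmetic of the 2:6
average homologue ratio under 50% mosaicism supports ten copies on the
derivative, and the fixture encodes ten; the alternative published reading
of "about eight copies" corresponds to the population-average total of
eight and is recorded here rather than silently reconciled.

Several fixture chromosomes genuinely lack an array-visible subtelomere at
one end (terminal deletions, the amplified der(6), the der(20) short arm).
They carry an explicit per-end `assume_telomere` annotation — the model's
counterpart of assuming a healed or cryptically capped telomere — and the
viability checker honours it; without the annotation those members report
`unterminated`, which the tests assert.

The event vocabulary extends the classical set (deletion, duplications,
amplification, translocations, whole-genome duplication) with chromosome
gain/loss and a duplicative `segment_capture` kind. Both are required to
express the fixture: trisomies and clone-specific losses cannot be written
as interval events, and several derivatives carry copied fragments whose
donor chromosomes remain intact.

## The scenario generator

`generate_scenario()` draws seeded random event histories on a
three-chromosome diploid genome (default chromosomes 10–12, ~12k probes at
default density — sized so that hundred-scenario studies run in minutes on
one CPU; the acceptance checks use 100 scenarios for parameter recovery
and 50 + 50 for capture detection). Ancestral events are shared by both
clones (default fractions 0.6/0.4); subclonal events are single-copy
deletions/duplications so their cell fraction is identifiable (see the
enumeration family above). Event sizes are log-uniform on 0.5–50 Mb;
breakpoints avoid centromere intervals, where arrays have no probes;
infeasible draws are redrawn and counted. The capture toggle constructs
one centromere-capture marker: acentric head and tail fragments of a host
chromosome rescued by a 2–6 Mb pericentromeric donor fragment.

What the simulations do **not** emulate: GC waves and other platform
artefacts, probe drop-out, genotyping-cluster asymmetries, more than two
clones per scenario, metaphase-level FISH signal noise, and breakpoint
microhomology structure. Passing the recovery studies therefore shows the
inference is correct under clean mixture statistics at realistic noise and
density, not that it is robust to platform-specific artefact structure.

## Known limitations

* Segment-level inference constrains only population-average homologue
  dosage; clone decompositions beyond two clones, or with multi-copy
  subclonal jumps, are reported as their average (the amplified 6p21.3
  segment is called as its 2:6 average, with the ten-copy reading derived
  arithmetically).
* Band extraction cannot separate bands closer than the minimum separation
  (0.08), which caps usable per-clone totals near twelve copies.
* Homologue assignment needs dosage asymmetry somewhere on the chromosome;
  disjoint single rearrangements on a balanced background are reported
  `ambiguous`, and phasing against population reference panels is out of
  scope.
* Composition is unordered without adjacency evidence; breakpoint-graph
  assembly and rearrangement-history parsimony are out of scope.
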