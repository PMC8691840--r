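---
title: "crisprki methods: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crisprki methods: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprki)
```

This vignette documents the quantitative models behind each module, the
rationale for the default parameters, and the validation strategy. The
workflow it implements: fluorophore cassettes knocked into endogenous
loci with PCR-amplified donors carrying short (30–40 bp) homology arms
and 5′ biotin; integrations verified by whole-genome sequencing against
an insert-augmented reference and by Sanger reads across the junctions;
and cell-cycle state read out from a single-channel endogenous PCNA
fusion reporter.

## Coordinate convention

All coordinates are 1-based and closed. An insertion coordinate (donor
junction, integration call, planted-truth position) is the index of the
**last host base before the inserted sequence**. Guide cut sites use the
same convention: for a plus-strand protospacer starting at $s$, the
SpCas9 blunt cut falls between positions $s+16$ and $s+17$ and is
reported as $s+16$; on the minus strand the mirrored arithmetic gives
$s+2$ for a protospacer whose 23-mer footprint starts at $s$.

## Design module

**Cassette.** `build_tag_cassette()` strips the tag ORF's start codon
and stop codon so the insert reads through in frame with the host gene,
and rejects internal in-frame stops and off-frame linkers. A 720-nt ORF
yields a 714-nt cassette; with 33-bp arms the donor totals 780 bp.

**Homology arms.** `extract_homology_arms()` copies the arms verbatim
from the genomic window flanking the insertion point. It warns outside
the recommended 30–40 bp range (the short-arm regime the protocol
depends on) and errors only when an arm would leave the window.

**Donor molarity.** `donor_molarity(ng_per_ul, length_bp)` uses
$c_{nM} = 10^6 \cdot m / (650 \cdot L)$ with 650 g/mol per base pair.
At 10 ng/µl a 780-bp donor is 19.7 nM — the arithmetic behind using
short PCR donors at high molarity instead of long cloned constructs.

**Primers.** Donor amplification primers anneal to the cassette ends,
carry the full homology arms as 5′ tails, and are 5′-biotinylated
(suppressing donor concatemerization in vivo). Genotyping primers are
placed strictly outside the donor footprint so they cannot amplify
residual donor; the knock-in amplicon exceeds the wild-type amplicon by
exactly the cassette length. `simulate_pcr()` is a strict in-silico PCR
(exact primer matches, unique orientation) used both for validation and
for predicting amplicon sizes.

## WGS verification module

Reads are mapped with a naive seed-and-extend mapper
(`map_reads_naive()`; exact k-mer seeds, ungapped extension, best
mismatch count, MAPQ 60/unique vs 0/tied) against the host genome
augmented with the known insert contigs. The mapper exists only to make
the synthetic path self-contained; real alignments enter through
`read_sam()`.

Evidence is combined in three stages:

1. **Anchor pairs** — read pairs with exactly one mate on an insert
   contig. The host mate's strand gives the junction side.
2. **Clusters** — per contig and side, single-linkage clustering of
   anchor positions with a 500 bp gap (about one fragment length);
   clusters below 3 supporting pairs are not called but are tallied as
   `subthreshold` diagnostics.
3. **Calls** — left/right clusters pair within 1 kb. When soft-clipped
   split reads (≥ 10 clipped bases) exist, the junction coordinate is
   resolved **jointly from both clip sides** by modelling the mapper's
   own extension rule (ungapped, match +1 / mismatch −3, maximum-scoring
   run kept): a right-clip at $q_R$ is consistent with a coordinate
   $p \le q_R$ when extending the insert *head* against the host after
   $p$ under that scoring first peaks exactly $q_R - p$ bases in; a
   left-clip at $q_L$ with $p \ge q_L$ when the absorbed insert-*tail*
   bases keep every running prefix score non-negative. This covers both
   exact micro-homology (probability 1/4 per junction of at least one
   shared base, so one-sided "left-alignment" normalization would
   mis-place roughly a quarter of junctions) and near-match overshoot
   (one mismatch followed by several matches still scores positive, so
   the raw clip can land past the junction). The true coordinate lies
   in both candidate sets, and their intersection is almost surely
   unique; in the rare cases where the clip coordinates alone cannot
   separate two neighbouring candidates — both hypotheses predict the
   same raw clips when the insert termini and flanking host share
   bases — the soft-clipped read *content* breaks the tie, because the
   clipped bases must continue the insert head (right clips) or end at
   the insert tail (left clips) at the offset each candidate implies.

**Copy number.** The insert/host depth ratio (aligned bases per contig
base) classifies calls: a heterozygous single copy puts the insert on
one of two haplotypes, so the expected ratio is 0.5; calls in
[0.25, 0.75] are `single_copy_het`, above 0.75 `multi_copy_or_concatemer`
(a 3× tandem concatemer on one haplotype expects 1.5), below 0.25
`partial_low_support`.

**Validation.** `wgs_recovery_study()` runs seeded 100-kb / 714-bp /
20× / 150-bp / 0.1%-error simulations: the called coordinate equals the
planted junction exactly in ≥ 95/100 heterozygous runs, insertion-free
runs produce zero calls, and the het/concatemer depth-ratio classes
separate in ≥ 95/100 runs each.

## Junction classification module

`classify_junction()` aligns an observed Sanger read to the expected
homology-directed-repair allele, requiring ≥ 40 bp of aligned flank on
both sides of the junction. The inserted/deleted segment between the
maximal exact left and right matches is normalized over its placement
ambiguity and parsed: if a prefix of the inserted segment exactly
duplicates the homology-arm sequence adjacent to the breakpoint and is
at least 6 bp (`min_dup`), the event is a `partial_duplication` with
the remainder reported as `ins_seq` — the study's characteristic
imperfect-repair signature, e.g. a 21-bp arm duplication plus 7-bp
insertion 22 bp upstream of the start codon (coding unaffected), or a
26-bp duplication 4 bp after the stop codon. Offsets are reported
relative to the nearest coding feature (start or stop codon), and
`coding_affected` is true only when the event overlaps coding sequence
or shifts the reading frame.

## Cell-cycle module

All statistics come from a circular nuclear ROI.

- **Intensity trace**: ROI mean per frame, normalized by the first
  frame's value.
- **Width trace**: per frame, the pixel-intensity histogram over a
  global range (256 bins), summarized as the distance between the
  outermost bins reaching 5% of the peak bin's occupancy. This simple
  occupancy width responds monotonically to pixel-value dispersion and
  is robust to the absolute intensity level.
- **Speckles**: local maxima above mean + 2 SD of the ROI, with a
  minimum prominence over the surrounding ring (default 500 intensity
  units for 16-bit movies) and 2 px mutual separation.

`segment_phases()` applies the reporter's decision rules in order: the
earliest ≥ 30% drop of the normalized trace relative to its recent
maximum marks **M onset** (nuclear envelope breakdown releases PCNA);
the smoothed-width argmax marks the **S/G2 transition** (PCNA
redistributes into the largest pixel-intensity spread at the end of S);
frames before it with positive robust (Theil–Sen) local slope are **S**,
refined to **late S** when ≥ 3 speckles are present; frames between the
width peak and M onset are **G2**; a track with no division and a
negative overall slope is all **G1**.

**Movie generator.** `simulate_nucleus_movie()` programs the ROI mean
per phase (G1 exponential decay at 0.0015/min; S multiplicative rise of
2.6%/frame; G2 flat; M dropping 45%/frame over 2 frames), adds six
Gaussian replication foci (amplitude 2600) during late S, and adds a
dispersed bright-pixel component to a fixed half of the ROI pixels
(avoiding the foci) with amplitude $A_f = 4000 \cdot 0.7^{|f -
t_{S/G2}|}$ over late S and G2 — a geometric tent that peaks exactly at
the programmed S/G2 frame. The tent shape is deliberate: the dispersion
must exceed the speckle intensity reach only near the S/G2 frame (so
the width estimator peaks there), while staying small earlier in late S
(so the speckle detector's mean + 2 SD threshold still finds foci).
Gaussian camera noise (SD 25) is added everywhere and values are
clamped to 16-bit. Defaults mirror the study's imaging: 20 min/frame,
68 frames, S/G2 at frame 48 (940 min), M onset at frame 61 (1200 min).

**Validation.** `movie_recovery_study()` over 100 seeded movies:
|t_SG2 − truth| ≤ 2 frames and |t_M − truth| ≤ 1 frame in ≥ 95 runs
each, mean frame-wise label agreement ≥ 0.90, and G1-only movies come
out all-G1.

## Simulators

`simulate_locus()` (random window with a clean ORF),
`plant_insertion()` (tandem copies, het/hom, with truth), and
`simulate_read_pairs()` (uniform fragments, Normal(400, 60) lengths
truncated at the 150-bp read length, i.i.d. substitution errors at
0.1%, constant Q37 qualities since the error model is
substitution-only) are deterministic per seed and emit the full ground
truth. Pair counts follow $n = \mathrm{depth} \cdot L / (2 \cdot
\mathrm{read\_len})$ per allele with the total depth split across
alleles.

## Problem sizes and runtime

Single-CPU, one run each: design on a 2-kb window — milliseconds;
WGS verification of a 100-kb host at 20× (~6,700 pairs) — about 2 s;
junction classification — milliseconds; a 68-frame 64×64 movie —
about 0.3 s to analyze. The 100-run studies complete in roughly 8 min
(WGS, three scenarios) and 30 s (movies).

## Limitations

- The naive mapper is ungapped and exact-seeded; it serves the
  synthetic path only and is not a general-purpose aligner. Real data
  should be aligned externally and ingested as SAM.
- The read simulator has no indel errors, quality-dependent errors, or
  coverage bias; the movie simulator has no photobleaching, PSF, or
  nuclear movement (the ROI is static).
- Guide scanning reports all NGG protospacers near the cut site sorted
  by cut-to-junction distance; it does not score genome-wide
  off-targets (the study used external web tools for that).
- Copy-number classification assumes a pooled heterozygous F1 design;
  mosaic founders would need different depth bands.
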