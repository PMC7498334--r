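---
title: "Methods: UMI-aware amplicon bisulfite analysis of imprinted regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UMI-aware amplicon bisulfite analysis of imprinted regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampmeth)
```

## The assay model

An amplicon panel targets short (≤ 430 bp) bisulfite PCR products over
imprinting control regions (ICRs) and over always-unmethylated and
always-methylated control regions. Each product is defined by CpG-free
primers, carries at least five CpGs, and is amplified from one chosen strand
of the bisulfite-converted genome. The reverse primer tail contains eight
random nucleotides that become a unique molecular identifier (UMI): every
PCR copy of one original molecule carries the same UMI, and paired-end
2 × 250 bp sequencing reads it out as the first 8 bases of read 2.

Bisulfite chemistry is modelled at the base level: an unmethylated cytosine
on the targeted strand deaminates and is read as T with probability
`conversion_rate`; a methylated CpG cytosine is erroneously read as T with
probability `inappropriate_conversion`. All non-CpG cytosines are treated as
unmethylated, which is what makes them usable as a built-in conversion
control: the fraction of non-CpG cytosine observations read as T is reported
as the conversion efficiency.

Coordinates are 0-based half-open internally; every CpG is keyed by the
top-strand position of its C regardless of which strand the amplicon
targets, so top- and bottom-strand amplicons produce directly comparable
tables. For a bottom-strand amplicon the same chemistry is observable in
top coordinates as G→A substitutions, and calls use the mirrored G/A logic.

## Pipeline stages and their assumptions

1. **UMI extraction** — the first 8 bases of read 2 move into both read IDs
   after a final `:` separator; pairs whose read 2 is not longer than the
   UMI are rejected and counted.
2. **Trimming** — a deliberately minimal quality/adapter trimmer: the
   trailing run of bases below Phred 20 is removed, then a 3′ adapter match
   (≥ 3 bases overlap, ≤ 10% mismatch, longest match wins) is cut, and
   pairs with a mate under 20 bases are discarded. Simulated reads are
   clean; this stage exists so real FASTQ behaves plausibly. Exact
   Cutadapt semantics (alignment-scored matches, 5′ adapters) are not
   reproduced.
3. **Amplicon assignment** — reads start at the primer, so alignment is
   anchored and ungapped: the first 30 bases of read 1 are compared in
   three-letter space (C and T collapsed, i.e. blind to methylation)
   against each amplicon's converted targeted-strand prefix. The best
   amplicon wins if its mismatch fraction is ≤ 10% *and* it beats the
   runner-up by ≥ 2 mismatches; ties and poor matches are reported as
   unassigned rather than silently dropped. The 30-base anchor and 2-
   mismatch margin keep assignment unambiguous on any rule-compliant panel
   at up to ~10% per-base error; both are arguments.
4. **CpG and SNP calling** — ungapped placement of read 1 (offset 0) and
   reverse-complemented read 2 (anchored at the amplicon end) on the
   targeted strand. At each CpG cytosine: C ⇒ methylated, T ⇒
   unmethylated, anything else (including uncovered) ⇒ unknown. Where
   mates overlap, read 1's call wins, preventing double counting of one
   molecule. Non-CpG reference cytosines observed as C accumulate in an
   `unconverted_noncpg` counter; reads with ≥ 3 such failures are flagged
   conversion-suspect but retained (controls are separate amplicons; no
   filter is applied).
5. **Deduplication** — reads group by (amplicon, read-1 start, UMI); the
   targeted strand is an amplicon property so it is implicit in the key.
   One representative per group is kept: the first after a stable sort by
   read id, which is deterministic across platforms (a first-seen rule
   would depend on input order). UMI matching is exact by default; a
   1-mismatch collapsing mode exists for real data with UMI sequencing
   errors and is off by default.
6. **Allele splitting** — a SNP is usable only if its two alleles remain
   distinguishable after conversion under any methylation assumption
   (C/T pairs masked on top-strand amplicons, G/A on bottom). Each covered
   usable SNP votes with conversion-aware matching (allele C matches
   observed C or T on the top strand); unanimous votes assign the read, a
   single informative SNP suffices, conflicting votes mark the read
   unassigned-with-conflict. Conflict/unassigned reads stay in the overall
   quantification but are excluded from per-allele tables — conservative,
   and symmetric between strains.
7. **Quantification and status** — per-CpG percentages over deduplicated
   reads; the region mean is the *unweighted* mean over CpG percentages
   (matching per-CpG quantification, not a read-weighted pooled rate).
   Read-level classes use strict inequalities (> 90% methylated, < 10%
   unmethylated, exactly 90% is intermediate) and require ≥ 3 called CpGs
   so that 1-CpG fragments cannot polarize the class fractions. Regions
   need strictly more than 100 deduplicated reads; at 100 they are
   `low_coverage` and excluded from status interpretation. ICR status uses
   the 40–60% normal band. The approximate field thresholds are hardened
   to these strict numeric rules and live in `quant_thresholds()`, all
   overridable.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `conversion_rate` | 0.995 | probability | typical good bisulfite kit efficiency |
| `inappropriate_conversion` | 0.005 | probability | over-conversion of methylated C |
| `seq_error_rate` | 0.001 | per base | MiSeq-scale substitution rate |
| `read_len` | 250 | bp | paired 2 × 250 chemistry; spans any ≤ 430 bp product with its mate |
| `umi_len` | 8 | nt | fixed by the primer design |
| `mean_pcr_copies` | 1.25 | copies | ~20% expected duplication, inside observed assay ranges |
| `min_region_reads` | 100 | reads | coverage threshold, strictly exceeded |
| `read_meth_hi` / `read_meth_lo` | 90 / 10 | % | fully methylated / unmethylated read cutoffs |
| `normal_band` | 40–60 | % | expected ICR bulk methylation |
| `min_cpgs_called_per_read` | 3 | CpGs | stabilises read classes |

## What the simulator emulates — and what it does not

`simulate_reads()` draws, per amplicon: parental origin per molecule
(`maternal_fraction`, default 0.5), independent per-CpG methylation bits
from that parent's probabilities, strain SNP alleles from the parental
labels, one stochastic bisulfite conversion per molecule (conversion
happens before PCR, so copies share it), a shifted-Poisson PCR copy number
(`1 + Poisson(mean - 1)` — one parameter, guarantees every molecule is
sequenced), a shared UMI per molecule drawn uniformly over 4^8, and fresh
per-copy sequencing errors. Base qualities are constant Q37: the error
model is substitution-driven, and quality trimming is exercised separately
with constructed low-quality tails. Whole-allele deletions
(`allele_deleted`) emulate patient genotypes such as a deleted maternal
ICR, which must read ~0% methylated.

With 1000 molecules sharing one start coordinate, uniform 8-nt UMIs
collide occasionally (about 7–8 pairs expected by the birthday bound), so
deduplicated counts sit just below the molecule count; `umi_mode =
"unique"` samples UMIs without replacement where exact molecule recovery
is being verified. Collisions against the truth table are detectable
because the truth records each molecule's UMI.

Not modelled: indels (so real indel-bearing reads become unassigned, by
design of the ungapped aligner), per-cycle quality decay, chimeric or
primer-dimer artifacts, insert-size variation (amplicons are
primer-delimited), and amplification bias between methylated and
unmethylated alleles — the assay measures that bias rather than assuming a
law for it, so the simulator defaults to none; the
`methylation_shift_check()` QC reports the pre/post-deduplication shift
that such bias produces, and a forced-duplication fixture in the tests
shows the deduplicator removing it. Passing tests therefore demonstrate
correctness of the computational method under controlled chemistry, not
robustness to every artifact of real libraries.

## Numerical and degenerate-input choices

- Percentages are plain ratios; a CpG with no called reads reports `NA`
  rather than 0, and a region whose CpGs are all uncalled reports `NA`
  mean and `low_coverage`.
- 'N' reference positions carry no CpG and no SNP; any read base other
  than C/T (or G/A on bottom strand) at a CpG is an unknown call.
- Amplicon-assignment ties (identical three-letter anchors) are warned
  about at panel validation and yield unassigned reads at run time.
- All stochastic stages consume one seeded RNG stream
  (`simulate_reads(seed = )`), giving byte-identical FASTQ and reports on
  rerun; the pipeline itself is deterministic.
- The synthetic panel (`synthetic_panel()`) is built from an internal
  deterministic generator, never from the session RNG, so fixtures cannot
  drift.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data at
desk scale: 1000 molecules per amplicon (~1250 read pairs after PCR) for
the recovery checks, 60–400 molecules for exactness, deduplication-oracle
and reciprocal-cross checks. These sizes put binomial noise on a region
mean near ±1.6 percentage points (n ≈ 1000 reads × 12 CpGs), comfortably
inside the 40–60% decision band while keeping a full run in seconds to a
couple of minutes on one CPU.

## Known limitations

- The trimmer is intentionally simplified; heavily degraded real libraries
  should be pre-trimmed with a dedicated tool before import.
- Ungapped assignment cannot rescue indel-bearing reads; they are counted
  as unassigned rather than recovered.
- Amplicon-level sequencing-bias exclusion ("clear bias toward one allele
  or class") has no quantitative definition in the field; the package
  reports the diagnostics (allele split, class fractions, dedup shift) and
  leaves exclusion to the analyst rather than auto-filtering.
- Multi-sample barcoded libraries are expected to be demultiplexed
  upstream by the sequencer; the pipeline processes one sample per run.
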