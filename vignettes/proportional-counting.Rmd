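---
title: "Proportional counting on unique feature positions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proportional counting on unique feature positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniquant)
```

## The counting model

`uniquant` quantifies annotated features (by default `gene` rows of a GFF3,
keyed on the `ID` attribute) from a coordinate-sorted genome alignment of a
prokaryotic RNA-seq library. Two properties of bacterial data drive the
design:

* **Multigene fragments.** Operons transcribe several genes on one mRNA, and
  inter-gene gaps are often shorter than the sequencing fragment, so a
  properly paired fragment frequently spans more than one gene. Discarding
  such fragments systematically deflates operonic genes; counting them fully
  toward every overlapped gene inflates small genes near highly expressed
  neighbors.
* **Overlapping annotations.** Genes overlap on the same and opposite
  strands. Positions covered by two or more features cannot be attributed to
  either from a genome alignment alone.

The model resolves both with a single primitive, the **unique position**: a
genomic position covered by exactly one feature on the relevant strand key.
Per feature we precompute its set of unique intervals and its **unique
positional length** (`uniq_len`). Each countable unit — a fragment
reconstructed from a proper pair, or a single read — contributes to feature
`f`:

$$F_c = F_O / F_L$$

where `F_O` is the number of bases of the unit's span lying in `f`'s unique
intervals and `F_L` is the unit's total length. A unit entirely inside one
gene's unique territory contributes exactly 1; a junction-spanning fragment
splits its single count across the genes in proportion to overlap; bases over
ambiguous positions are simply lost. For units that could not be paired
(mate unmapped, discordant, |TLEN| at or above the fragment-size bound, or
TLEN 0), `F_c` is halved: both mates of a broken pair may be counted
separately, and halving caps their joint contribution at one fragment's
worth while discounting mappings that are more likely erroneous.

Consequences worth knowing: a feature fully covered by other features has
`uniq_len` 0 and can never earn direct counts (it is still reported, with
zeros); per-unit contributions satisfy `sum_f F_c <= 1` (`<= 0.5` for reads)
with equality exactly when every base of the unit is in someone's unique set.

## Alignment intake

Records are streamed in chunks (default 10 million records; results are
invariant to the chunk size) and validated: unmapped, secondary (0x100) and
supplementary (0x800) records are dropped, as are records below the
inclusive MAPQ threshold (default 10). A record is processed as a
*fragment* when it is properly paired (flag 0x2), its mate maps to the same
contig, and `0 < |TLEN| < max_fragment_size` (default 1000, exclusive);
only the leftmost mate (TLEN > 0) emits the unit, spanning
`[pos, pos + TLEN)`, since the mate adds no information. Everything else
kept becomes a *read* unit covering its aligned reference span (CIGAR
M/D/N/=/X operations; soft clips excluded; no splice awareness — the span is
leftmost-to-rightmost, so the unsequenced inner gap of a pair counts as
overlap). `keep_only_proper_pairs` drops read units entirely.

For stranded libraries (`stranded = "yes"` or `"reverse"`), a fragment's
strand is that of the first-in-pair read (flipped for `reverse`), and the
index is built per strand; unstranded runs use one strand-agnostic key per
contig. Unpaired units use the read's own orientation, which for a
second-in-pair singleton in a forward library is the opposite of the
fragment's — a deliberate simplification, acceptable because singletons are
already half-weighted; library dialects whose singletons are predominantly
second-in-pair would need the flip.

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
SAM positions are converted once at parse time, which keeps every overlap
computation free of off-by-one cases. Rows of the GFF3 sharing one
identifier (multi-interval features) are merged into one feature whose
unique set is computed from the union of its intervals. Features on contigs
absent from the alignment are kept and report zero counts.

## EM rescue of multimapped records

Records whose `NH` tag exceeds 1 are not counted directly. Their
(template, feature, `N_r,f`) contributions are deferred until all uniquely
mapped records are processed, then folded in iteratively:

$$a_{r,f} = N_f / N_{r,F}, \qquad \sum_{f} a_{r,f} = 1$$
$$N_{f,k} = N_{f,0} + \sum_{r} a_{r,f}\, N_{r,f}$$

Iteration 1 uses the uniquely-mapped-only counts `N_f,0` as the abundance
anchor; each later cycle recomputes the weights from the previous `N_f,k`.
The default is `K = 1` iteration; `em_iterations = 10` is a reasonable
setting when multimapping is heavy, as the iteration converges within a
handful of cycles on realistic inputs (the per-iteration delta
`sum_f |N_f,k − N_f,k−1|` is exposed via `convergence_series()`).
`remove_multimapped` drops NH > 1 records at validation instead and is
equivalent to `K = 0` plus excluding those units from the alignment tally.

Numerical choices: a record whose overlapped features all have zero current
count is split equally among them (maximum-entropy choice; dropping it would
silently destroy count mass and make conservation untestable). No
convergence-based early stopping is done by default, keeping runs
deterministic for fixed `K`; `em_tol` enables it. By default only primary
records represent a multimapped template, so the EM can only reinforce the
primary locus; `include_secondary = TRUE` admits the secondary alignments of
NH > 1 templates (whose MAPQ, conventionally 0, is then not held against
them) so the EM genuinely weighs alternative loci. `num_alignments` counts
every retained unit overlapping the feature, multimapped included,
regardless of EM weighting.

## Output

TPM is computed on unique positional lengths: `rate_f = N_f,K / uniq_len_f`
(0 where `uniq_len` is 0), scaled so that TPM sums to one million whenever
any count is nonzero. The output table has five tab-separated fields —
feature ID, unique length, overlapping-alignment count, fractional counts,
TPM — one row per annotated feature in annotation order, zero-count features
included (stable schema across samples), counts and TPM printed with two
decimals.

## The synthetic fixture generator, and what it does not emulate

`make_fixture()` builds GFF3 + SAM pairs for six geometries: `operon`
(genes sharing a transcript, with junction-spanning fragments; one interior
gene is half-length to expose length bias), `overlap_pair` (a shared
interior interval), `neighbor_readthrough` (3' UTR read-through barely
reaching a small downstream gene), `multimap` (a duplicated locus, NH=2,
one primary per template plus secondary records at the other copy),
`singleton_mix` (pairs plus mate-unmapped singletons) and `stranded_mirror`
(one layout emitted in forward- and reverse-stranded dialects). Fixtures are
plain SAM so the test suite needs no external binaries; quantification
converts them to BAM internally via Rsamtools.

For the operon and read-through scenarios, fragment starts are tiled
*evenly* over the transcript span extended by one fragment length of UTR on
each side. This emulates uniform sampling from the full polycistronic mRNA
— the situation in which a proportional counter should give every operon
gene the same length-normalized expression — while keeping the expectation
exact rather than stochastic; without the UTR extension the terminal genes
would be under-covered purely by construction. Scenario geometry defaults
(300 bp genes, 20 bp gaps, 250 bp fragments, 100 bp reads, about 10–50
fragments per gene) are desk-scale caricatures of bacterial data chosen so
that the whole validation suite runs in seconds on one CPU; the per-base
oracle makes the expected counts exact at any depth, so scale adds nothing
but runtime.

Each fixture ships a truth table computed by `oracle_counts()`, a
deliberately naive per-base enumerator (label every position with its unique
owner, walk every unit base by base, add `1/F_L` — halved for reads — to
each base's owner) that shares no interval machinery with the main path.

The generator is *not* a read simulator: no sequences, qualities,
sequencing errors, coverage biases, or alignment artifacts. Passing tests
therefore demonstrate the counting semantics — proportional assignment,
ambiguity exclusion, EM behavior, strandedness, invariances — not robustness
to alignment noise, annotation errors, or biased coverage in real
libraries.

## Known limitations

* Span-based `F_L` uses |TLEN|; mates overlapping each other double-cover
  bases but are still measured by span, and the unsequenced inner gap counts
  as overlap.
* Not splice aware; `N` CIGAR gaps count toward a read unit's span.
* Features crossing a circular-contig origin are treated as linear
  intervals.
* No fragment-length or positional bias model — the EM redistributes by
  abundance only.
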