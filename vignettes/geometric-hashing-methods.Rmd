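---
title: "Seed finding and geometric hashing: models, parameters and design choices"
author: "geoseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed finding and geometric hashing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoseed)
```

## The problem

Seed finding is the first phase of most homology search and genome
alignment pipelines: before any alignment is attempted, pairs of
positions — *seeds*, or alignment anchors — are proposed where the two
sequences look locally identical. Everything downstream (gapless
extension, chaining, full alignment) is anchored at these positions, so
the seed set must be found fast, must contain nearly all truly
homologous position pairs (sensitivity), and must not drown the
extension phase in random hits (specificity).

`geoseed` implements a family of seed finders and, on top of them, two
filters that raise specificity by exploiting where seeds lie relative to
one another rather than what their sequence context looks like:

* **contiguous k-mer matching** — an exact match of length $k$ at window
  starts $(a, b)$ yields the midpoint seed;
* **spaced-seed matching** — a binary pattern
  $p \in \{0,1\}^\ell$ of weight $k$ (number of 1s) and span $\ell$ is
  slid along both sequences; the *induced k-mer* at window start $a$
  concatenates the residues at the pattern's match positions, and equal
  induced k-mers in the two genomes yield a seed. Sets of patterns of
  equal weight are matched jointly (a hit for *any* pattern counts);
* **neighbouring-matches filter** — a candidate $(i, j)$ survives only
  if enough candidates lie on the same alignment diagonal
  $i - j = \mathrm{const}$ within a window of $D$ bp around it;
* **geometric hashing** — candidates are pooled over *long* distances:
  each candidate is hashed to a tile
  $(S_1, S_2, \lfloor (i-j)/F \rfloor)$, tiles are scored, and all
  members of tiles reaching a threshold are reported.

## The geometric hashing model

Orthologous genes carry several conserved exons separated by introns
whose lengths drift apart between species. Seeds from different exons of
one ortholog pair may be tens of kilobases apart, yet their diagonals
$i - j$ agree up to the cumulative intron-length difference. Quantizing
the diagonal into tiles of width $F$ collects them: with
$g(S_1,i,S_2,j) = (S_1, S_2, \lfloor (i-j)/F\rfloor)$, any two members
of one tile satisfy $|(i-j) - (i'-j')| < F$.

A tile is scored by how strongly its members cluster. It is divided into
$b$ sub-tiles (by the within-tile diagonal remainder $d = i - j - F
\lfloor (i-j)/F\rfloor$, sub-tile $\lfloor d\,b/F \rfloor$) and chunks of
length $h$ along the anti-diagonal (chunk $\lfloor (i+j)/h \rfloor$).
With $n_{r,s}$ the candidate count in sub-tile $r$ and chunk $s$,

$$\mathrm{Score}(t) = \frac{1}{\lambda\, b\,(s_{\max}+1)}
  \left(\sum_{r=0}^{b-1}\sum_{s=0}^{s_{\max}} n_{r,s}^{\,p}\right)^{1/p},$$

where $\lambda = A L / (n_1 n_2)$ is the expected count per chunk if all
$L$ candidates of the run were scattered evenly over the alignment space
($A = hF/b$ is the chunk area; $n_1, n_2$ are the *total* input lengths
per genome, pooled over everything that entered the run), and
$s_{\max}$ is the largest chunk index any admissible position pair of
the tile can reach. The $p$-norm rewards concentration: $c$ candidates
in one chunk outscore the same $c$ spread over $q$ chunks by a factor
$q^{1-1/p}$.

Seeds of tiles with $\mathrm{Score} \ge \tau$ are reported; all others
are dropped. Because the evidence is pooled across a whole diagonal
band, a single random match almost never survives, while a gene with
several conserved exons passes easily even when individual exons yield
few matches.

### Assumptions

* Homology manifests as substitution-only local identity; indels are
  absorbed between seeds (by the tile width), not within them.
* Only horizontal shift relates the two copies — no inversion or
  strand change is modelled; only the forward strand is represented.
* Random (non-homologous) sequence behaves approximately like i.i.d.
  uniform nucleotides for the purpose of the normalization $\lambda$ and
  the false-positive model.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| $k$ (weight) | 15 | bases | match positions per pattern; each unit quarters the random match rate |
| $m$ | 4 | patterns | patterns matched jointly; sensitivity grows, random rate grows linearly |
| cap | 10 | pairs/k-mer | per-(pattern, k-mer) subsample of candidate pairs, curbing repeats (weight-12 runs conventionally relax it to 100) |
| $D$ | 1000 | bp | neighbouring-matches window (count within $|i-i'| \le D/2$) |
| $\tau$ (M4) | 2 | seeds | required same-diagonal count, candidate included |
| $\ell$ | pattern span | bp | non-overlap distance between counted matches |
| $F$ | 10{,}000 | bp | tile width; sized so most vertebrate ortholog pairs keep all exons in one tile |
| $b$ | 50 | sub-tiles | diagonal resolution within a tile |
| $h$ | 400 | bp | chunk length along $i+j$; roughly 2–3 exon lengths |
| $p$ | 6 | — | norm exponent; the fullest chunks dominate the score |
| $\tau$ (score) | calibrated | — | tile score threshold (see below) |
| $k'$, $\tau'$ | 19, 3 | — | two-step preset: coarse pass weight and tile link-count threshold |

The tile width is a trade-off. The maximal exon offset
$\Omega = \max_i |(a^1_i - a^1_1) - (a^2_i - a^2_1)|$ of an ortholog
pair (computed by `maxExonOffset()`) measures the cumulative intron
drift a tile must absorb; $F$ should exceed typical $\Omega$, while very
large $F$ invites spurious co-tiling. For vertebrate-like intron drift
the conventional $F = 10^4$ keeps roughly three quarters of ortholog
pairs in a single tile; organisms with shorter introns warrant smaller
$F$.

### Calibrating the score threshold

No universal $\tau$ exists: the score scale depends on input sizes
through $\lambda$ and $s_{\max}$. `calibrateScoreThreshold()` simulates
i.i.d. uniform sequences of the same per-genome lengths as the intended
input, runs the identical seed finding and tile scoring, and takes the
maximum null tile score over `nrep = 3` replicates times a margin of
1.5. The margin covers the sampling fluctuation of an extreme statistic:
the null maximum is typically set by a chunk holding 2–3 candidates, and
one more candidate in that chunk rescales the maximum by at most ~1.5.

One consequence of the definition of $\lambda$ matters for small
studies: $L$ counts the candidates of the *actual* run. In genome-scale
inputs random matches dominate $L$ (they grow with $n_1 n_2$; exonic
matches only with gene count), so a null simulation has the same
$\lambda$ as the real run. In a small planted-gene study the exonic
candidates can dominate $L$ and deflate all scores relative to the null
calibration. The package therefore evaluates planted-gene studies the
way the statistic is defined — genomic and artificial sequences pooled
into one run, with $n_1, n_2$ their combined lengths — which restores
comparability and is how the whole-run normalization is meant to be
used.

## Conventions and numerical choices

* **Coordinates** are 0-based, half-open everywhere inside the package;
  GFF3's 1-based inclusive intervals are converted at the I/O boundary.
  CDS support is evaluated on the closed position set
  $\{a, \dots, b-1\}$ of the internal interval $[a, b)$.
* **Midpoints.** The seed of a matching window pair is
  `start + floor(span/2)` in 0-based coordinates, for contiguous
  ($\mathrm{span} = k$) and spaced ($\mathrm{span} = \ell$) patterns
  alike; a single uniform rule avoids ±1 drift between methods, and
  CDS-support evaluation is insensitive to it.
* **Floors** round toward $-\infty$ (R's `%/%` and `floor()`), so
  negative diagonals quantize correctly; integer-truncating division
  would mis-tile them.
* **k-mer packing.** Induced k-mers are packed 2 bits per base into
  doubles (exact integers up to $2^{53}$), supporting weights up to 26;
  the matching index and joins operate on the packed values, and the
  textual k-mer remains the interface contract.
* **Masking and ambiguity** are tested at the pattern's match positions
  only: these are the residues actually compared. Don't-care positions
  may be masked or ambiguous. Mask filtering is toggleable; ambiguous
  match positions always reject a window.
* **Counting convention (M4).** "Total number of seeds on the diagonal"
  includes the candidate itself, so $\tau = 2$ demands one valid
  neighbour and $\tau = 1$ is the identity; `countSelf = FALSE`
  switches to pure-neighbour counting. The non-overlap rule
  $|i - i'| \ge \ell$ applies between the candidate and each counted
  neighbour. With mixed-span pattern sets, $\ell$ is the maximum span.
* **De-duplication.** A seed is a coordinate tuple; identical tuples
  arising from different patterns are collapsed before any counting,
  keeping the first pattern id. Outputs are canonically sorted so
  results do not depend on hash iteration order.
* **Subsampling** draws exactly `maxPerKmer` distinct pairs uniformly
  without replacement from the occurrence product of a k-mer — without
  materializing the product — under a caller-supplied RNG seed.
* **$s_{\max}$** is computed in closed form: $i + j$ increases along the
  diagonal direction, so its maximum over the band-rectangle
  intersection pins the reference coordinate at the smallest per-genome
  upper limit; the tests validate the closed form against a brute-force
  band scan. The normalization uses the full $(s_{\max} + 1)$ chunk
  count, including edge chunks that admit few positions.
* **Multi-genome generalization.** An $s$-genome candidate requires the
  identical induced k-mer in every genome; the tile key holds the
  $s - 1$ floored differences against the (arbitrary) reference genome
  1. Sub-tiles use the first difference's within-tile remainder and
  chunks use $\lfloor \sum_g i_g / h\rfloor$ — the higher-dimensional
  subdivision is not pinned down by the pairwise construction, so this
  concrete choice is ours; at $s = 2$ it reduces exactly to the
  pairwise formulas, which the tests assert. The chunk volume in
  $\lambda$ generalizes to $A = h F^{s-1}/b$.
* **Empty-tile and degenerate inputs.** Empty tiles score 0;
  $\lambda \le 0$ is an error (no normalization without candidates); a
  tile band that misses the sequence rectangle entirely is an error;
  patterns with leading or trailing zeros are rejected as meaningless.

## The synthetic data generator

The generator produces the two kinds of inputs the evaluation needs.

**Negative sets** are pairs of i.i.d. uniform `ACGT` sequences, the
standard null model for seed specificity; any seed between them is a
false positive by construction. `referenceNegativeSet()` reproduces the
reference conditions — 705 sequence pairs totalling 62.348 Mb and
56.197 Mb — with near-equal per-pair lengths (the real per-gene lengths
are not published; only the totals enter the expected match count
$m n_1 n_2 / 4^k$). A `scale` argument shrinks both totals linearly;
counts then shrink by `scale`$^2$.

**Positive sets** are planted ortholog pairs: per gene, exon sequences
are drawn once, genome 1 carries them verbatim and genome 2 a copy with
i.i.d. substitutions at rate $1 - \mathrm{identity}$ (uniform over the
three alternative bases), so `identity` is the *pairwise* per-base match
probability — 0.85 by default, the typical human–mouse CDS identity.
Introns and flanks are drawn independently per genome: flank lengths
from $[5000, 10000]$, intron lengths from $[500, 1500]$, exon counts
4–10 and exon lengths 60–250 bp (mean ≈155 bp, echoing the mean length
of uninterrupted CDS alignment fragments in human–mouse orthologs).
Independent intron draws make the realized $\Omega$ nonzero while
keeping it well below $F = 10^4$, so a gene's seeds fall into one or two
adjacent tiles. Each gene pair forms its own sequence pair, and truth
CDS intervals, homolog links and the realized $\Omega$ are emitted.

What the generator does **not** emulate: repeats and softmasked
content, GC and composition bias, indels within exons (intron-length
variation is the only indel proxy), splice-form differences, and
genuine evolutionary divergence structure. Tests passing on this data
therefore demonstrate the machinery — the matching, the filters and
their calibration — under the stated model, not performance on real
genomes; in particular the published sensitivity values on real
human–mouse orthologs cannot be reproduced from synthetic data, and the
corresponding checks here are property-based (retention of
exon-supporting seeds, zero false positives) rather than
value-matching.

## Problem sizes used by the tests

The bundled checks run the negative set at 1/10 linear scale (6.23 Mb +
5.62 Mb, one CPU, about a minute), where the expected seed count of the
four-pattern weight-15 run is ~1.3×10⁵ and scales back to full size by
the exact factor 100; oracle suites use sequences up to 2 kb and
candidate sets up to ~2000, where exhaustive brute-force comparison is
feasible; the planted-ortholog study uses 20 gene pairs (~0.5 Mb per
genome) with a matched-size negative set, across three RNG seeds. These
sizes were chosen so every check recomputes its quantity from scratch
in a desk-scale session.

## Bundled pattern sets

The pattern files under `inst/extdata/` provide working pattern sets of
weights 15, 14, 8 and 19 so that nothing external is needed. Computing
*optimal* spaced-seed patterns is out of scope — patterns are inputs,
and any optimizer's output can be supplied through the same one-pattern-
per-line format. The weight-15 set was chosen with minimal pairwise
match-position overlap (span 25), so that joint matching has negligible
seed-level redundancy across patterns, as optimized sets exhibit; the
expected redundancy of the set is computable in closed form from the
union weights and is ~0.01% of matches at the reference scale.

## Known limitations

* Weights above 26 are unsupported by the 2-bit packing.
* Reverse-complement matching is out of scope; inputs are compared on
  the given strand.
* The neighbouring-matches filter is defined for pairwise seeds only.
* `s_max` and tile scores assume each tile's sequence pair is present in
  the supplied lengths table; sequences that produced no candidates do
  not enter the per-genome totals unless passed explicitly via
  `genomeTotals`.
* The two-step variant selects tiles on raw pass-1 counts (threshold
  $\tau'$ plus ±1 offset neighbours), not on scored tiles; this mirrors
  its role as a cheap coarse pass.
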