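---
title: "The phosphomotif conservation index: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The phosphomotif conservation index: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A phosphomotif is a short positional pattern around a phospho-acceptor
residue, written in a PROSITE-like grammar: dash-separated tokens, `/`
for residue alternatives, `X` for a wildcard (`"R-X-X-S/T"`,
`"S/T-P"`). The acceptor is the first position whose residue set lies
within {S, T, Y}, overridable per motif for patterns with several such
positions.

For a motif and a set of its human phosphosites, conservation in genome
`q` is called through the ortholog-cluster multiple sequence alignment:
the human motif window is projected into alignment columns, and the
window counts as conserved in `q` if **some** member of `q` in the
cluster carries residues at exactly those columns that are all non-gap
and satisfy the pattern position by position. This is the strictest
reading of a "precisely matched" window: an indel anywhere inside the
window breaks the call even if an equivalent motif exists nearby in the
ortholog. We considered a variant that re-matches the pattern against
the ortholog's de-gapped local window, but rejected it: it makes the
call depend on an arbitrary search radius around the projected window,
and it decouples the motif call from the column-level homology the
alignment asserts. Strict column matching is the package's single,
documented behaviour.

The per-genome conservation rate is

    C_q = (# sites conserved in q) / (# human sites),

and the reference rate `R_q(r)` applies the identical machinery to
single-residue "motifs" over all background STY residues of the
phosphoproteins. The conservation index of the motif is

    CI = sum over q in G of (C_q − R_q),

with `R_q` the count-weighted mixture of `R_q(r)` over the motif's
actual acceptor residue types (an `S/T` acceptor whose sites are 70% S
contributes `0.7 R_q(S) + 0.3 R_q(T)`). The reference genome has
`C = R = 1` and contributes exactly zero, so CI is effectively bounded
by ±8 on the nine-genome panel. Positive CI means the motif's sites
are retained above what the acceptor residue's background drift would
predict.

## Conventions for missing data

Two situations provide no alignment evidence: a human protein assigned
to no ortholog cluster, and a genome absent from the protein's cluster.
Both count as **not conserved while staying in the denominator**. This
is the literal reading of "divided by the number of phosphosites
observed in the human genome", and since the same rule applies to the
reference rates the induced bias largely cancels inside `C_q − R_q`.
The alternative — restricting each genome's denominator to sites with
an ortholog present — is available as `denominator = "aligned_only"`
everywhere the rates are computed; note that it errors (rather than
silently returning 0/0) when a genome has no aligned site at all.

Other conventions, fixed once:

* a genome with several cluster members is conserved if **any** member
  matches; multiple human members of one cluster are evaluated as
  separate (protein, site) records;
* a human protein occurring in several clusters is assigned to the
  cluster covering the most genomes, ties broken by the smaller cluster
  id (the reassignment is logged);
* rates remain exact integer ratios until the final CI sum — there is
  no intermediate rounding;
* potential sites are scored by full-motif window matching, exactly
  like known sites; scoring them by acceptor-residue conservation alone
  would make the two CI axes incomparable, which defeats the purpose of
  the known-versus-potential comparison.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `genomes` | `sce spo cel dme dre cfa mmu ptr hsa`, ref `hsa` | ordered study panel |
| `denominator` | `"all"` | missing orthologs stay in the denominator |
| `class_size` | 10 | motifs per CI-rank bin |
| `alpha_p`, `alpha_fdr` | 0.01, 0.01 | enrichment cutoffs; significance needs both |
| `n_perm` | 999 | network permutations; p = (1 + #{null ≥ obs})/(1 + n_perm) |
| `background_max` | 20000 | cap on background STY sites for reference rates |
| `min_sites` | 3 (pipeline), 10 (kinase groups) | minimum support for a CI |

Reference rates are a background summary, so when the enumerated STY
background exceeds `background_max` the pipeline subsamples it with the
run seed rather than paying for millions of single-residue calls; at
20,000 sites the binomial standard error of each `R_q(r)` is below
0.005, an order of magnitude under the effects of interest.

Enrichment uses the upper-tail hypergeometric p-value with
Benjamini–Hochberg adjustment across terms. The resampling-based FDR of
older GO tools is deliberately replaced by BH: it is deterministic,
standard, and the double cutoff (`p < 0.01` and `FDR < 0.01`) is kept.

The network null draws node sets of the observed size uniformly without
replacement — the claim under test is "more than randomly selected
proteins", not "more than degree-matched proteins". A
`null = "degree_weighted"` switch samples nodes proportional to degree
as a sensitivity check; it is off by default.

Kinase substrate fractions count site-level kinase–substrate **edges**
by default (`unit = "protein"` counts distinct substrates instead):
substrate totals in the thousands are only reachable by edge counting,
and edges are the unit in which the underlying databases report
kinase–substrate relationships.

The known-versus-potential comparison reports the Pearson correlation
of raw CI pairs — the comparison is about the location of points
relative to the `y = x` diagonal on the CI scale, so a rank correlation
would discard exactly the information being plotted.

## What the simulator emulates — and what it does not

`simulate_families()` generates one protein and one ortholog family per
planted motif occurrence. Human sequences are uniform over the 20
residues; each non-reference ortholog retains the planted window as a
single Bernoulli block with probability `p_known` (or `p_potential`),
and every background position independently with probability `p_bg`,
substitutions being uniform over the 19 alternative residues. Failed
windows get an acceptor outside the acceptor set, so the window-level
conservation probability is *exactly* the configured value and the
closed-form expectation

    E[CI] = sum over q of (1 − loss_q)(p_site(q) − p_bg(q))

holds without approximation. Wildcard window positions are filled with
non-STY residues so planting never creates stray background
phosphosites. Decorative single-column insertions (rate
`indel_rate` per family) exercise the ungapped-position-to-column
mapping but are only ever placed outside planted windows and only in
non-reference rows, so planted truth is untouched.

The simulator deliberately omits: phylogenetic correlation along a tree
(each genome is an independent draw), realistic amino-acid composition
and substitution matrices (the pipeline only distinguishes
match/mismatch against residue sets, so a matrix would add nothing
testable), alignment errors, and detection bias in which sites get
labeled "known". Passing tests therefore demonstrate that the
*computation* is correct under controlled conditions — they do not
validate the biological assumptions of any particular alignment or
phosphosite database.

Default study conditions, chosen once: `p_bg = 0.5` (mid-range, maximal
binomial variance, hence conservative tolerances), `p_known = 0.8`
(a clearly conserved motif), protein lengths 150–250 for rate
calibrations (enough background STY per protein to estimate `R_q`
without contamination from planted sites) and 60–120 where only
mechanics are exercised. Validation problem sizes: 1000 planted sites
for null and effect-recovery checks (CI standard error ≈ 0.05), 2000
background sites for reference rates, 50 paired motifs × 20 sites per
class for the diagonal comparison, 999 permutations for network
p-values. Statistical checks use 3-standard-error tolerances derived
from the binomial counts actually observed, never hard-coded windows.

## Numerical and degenerate-input policy

* Readers are total on their documented dialects and fail loudly —
  unknown residues, non-integer positions, unequal alignment rows and
  missing columns are errors, not coercions.
* Empty site sets, empty edge sets and zero-denominator rates raise
  errors; nothing silently returns 0/0.
* Writers sort on fixed keys and format doubles to six significant
  digits, so identical inputs yield byte-identical files; the pipeline
  manifest contains no timestamps for the same reason.
* Ties in the CI ranking break on motif id; bins therefore partition
  the ranked list deterministically.
* All randomness (simulator, background subsampling, permutation
  nulls) flows from explicit integer seeds; there is no implicit
  entropy anywhere in the package.

## Known limitations

Conservation is called against a single precomputed alignment per
cluster; there is no alignment-quality filtering, no tree-aware
weighting of genomes (a chimp-conserved and a yeast-conserved site
count the same), and no ancestral-state reasoning. The kinase-group
substrate CI scores pooled sites by acceptor-residue conservation,
which is the only well-defined choice for substrates lacking a motif
assignment, but it is a weaker criterion than full-window matching.
Term annotations are taken as given and are not propagated over an
ontology graph.
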