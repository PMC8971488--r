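# shapesearch

Similarity search for RNA chemical probing reactivity profiles.

RNA structure probing (SHAPE reagents such as 2A3 and NAI, DMS, icSHAPE
readouts) assigns every nucleotide a *reactivity* — high for flexible,
unpaired bases, low for paired ones. RNAs that fold alike produce similar
reactivity profiles over the homologous region even when their sequences
have diverged past the reach of sequence alignment. `shapesearch` finds
structurally similar regions by comparing the reactivity signal directly:
a model-free, largely sequence-agnostic homology search for people who
have probing data for a molecule of interest and want to know where else
that structure occurs.

## The method in brief

BLAST-style seed and extend, with the continuous signal in place of the
sequence:

1. **Seed** — every query kmer (15 nt) whose capped reactivities have Gini
   coefficient ≥ 0.3 (windows inside uniformly paired/unpaired stretches
   carry no signal) is matched against the database by z-normalized
   Euclidean distance (the MASS subsequence-search measure, invariant to
   scale/offset differences between experiments), with a GC-content filter
   (±10 percentage points) and a promiscuity filter (no more than one
   match per 200 database nt).
2. **Group** — co-diagonal matches within 30 nt chain into high scoring
   groups (HSGs), the ungapped seeds.
3. **Extend** — each HSG is extended both ways by a banded three-state
   affine-gap DP over a piecewise-linear score of the reactivity
   difference `d = |rq − rd|` (match range (−0.5, 2), mismatch range
   (−6, −0.5), gap open −14, extend −5), stopping when the score stays
   below 0.8× the running best for more than 8 anti-diagonals. A
   `shape+sequence` mode additionally rewards base identity (+0.5/−2).
4. **Score** — the query is also searched against a database of 10-nt
   block-shuffled profiles (100 shuffles/entry, 1000-nt chunks); per-chunk
   best scores are fitted with a Gumbel extreme-value distribution
   (β = s√6/π, μ = x̄ − γβ) and each match gets
   `p = 1 − exp(−exp(−(S−μ)/β))` and `E = p × #(chunk-sized database
   pieces)`. Defaults report E ≤ 0.01 (shape-only) or E ≤ 0.005
   (shape+sequence).

Long queries are searched in 200-nt windows with 100-nt overlap and
consecutive matching windows are merged. Optionally, matched alignments
are folded with an RNAalifold-compatible engine (reactivity
pseudo-energies, Deigan slope/intercept per probe) and tested for a
significant consensus structure: 3-column-block shuffles of the alignment
build a null energy distribution, the true energy becomes a Z-score with
lower-tail normal p-value, and structures with p < 0.05 and ≥ 0.75
canonical base-pair support in every row are retained.

See `vignettes/shapesearch-methods.Rmd` for the full model, parameter
rationale and limitations.

## Worked example

Plant a homologous region into a synthetic database, search for it, and
read the report:

```r
library(shapesearch)

fx <- simulateBenchmark(n_queries = 3, query_len = 200, n_entries = 2,
                        entry_len = 2500, region_len = 150,
                        noise_sd = 0.15, identity = 0.8, seed = 7)
hits <- searchReactivityDb(fx$queries, fx$db,
                           shuffle_params = shuffleParams(n_shuffles = 100),
                           seed = 8)
hits[, c("query_id", "db_id", "query_start", "query_end",
         "db_start", "db_end", "score", "e_value")]
#>   query_id    db_id query_start query_end db_start db_end     score      e_value
#> 1  query03 target01           8       168      676    836 247.63251 3.402794e-26
#> 2  query02 target02           0       156      105    261 256.90393 7.336653e-25
#> 3  query01 target01          30        99      617    686  88.82223 5.167912e-08
fx$truth[, c("query_id", "query_start", "db_id", "db_start")]
#>   query_id query_start    db_id db_start
#> 1  query01          34 target01      621
#> 2  query02           0 target02      105
#> 3  query03          16 target01      684
```

Each row is one significant match: 0-based query and database intervals,
the alignment score, and its E-value — the expected number of equally good
chance matches in a database of this size. All three planted regions are
recovered at their planted positions (same diagonal as the truth table;
query01's is a partial recovery of the noisier copy) and nothing else is
reported at E ≤ 0.01. `mergeWindows(hits)` fuses
matches from consecutive windows of long queries;
`alignmentToProfileAlignment()` renders a hit for folding or Stockholm
output.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/shapesearch simulate --output-dir fixture --seed 7
Rscript inst/scripts/shapesearch search --query fixture/queries.db \
    --db fixture/targets.db --output-dir out --seed 8
```

Subcommands: `build-db` (RNA Framework-style reactivity XML or TSV → the
package's versioned text database), `shuffle-db`, `search`, `simulate`,
`benchmark`. Flags are kebab-case versions of the parameter names in the
R documentation (`--kmer-len` ↔ `kmer_len`, `--align-match-score` ↔
`match_min,match_max`, `--align-score-seq` ↔ `seq_scoring`, ...); every
stochastic stage takes `--seed`, and identical configuration plus seed
reproduces outputs byte for byte.

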