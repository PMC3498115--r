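# tpppscan

Domain-architecture classification and phyletic profiling of TPPP-like
proteins.

## The problem

Tubulin Polymerization Promoting Proteins (TPPPs) and their relatives form a
eukaryotic superfamily defined by a single sequence signature, the
**p25alpha domain** (Pfam05517 / IPR008907). The full ("long") domain spans
140–160 amino acids; its C-terminal 31–32 residues are exceptionally
conserved and also occur on their own, as the **partial p25alpha domain**,
whose hallmark is the glycine-rich Rossmann-like motif `GXGXGXXGR`
(glycines at motif positions 1, 3, 5 and 8, arginine at 9), followed — in
motif-bearing proteins only — by a conserved 14-residue extension block.
Family members sort into six architecture subfamilies:

| subfamily      | architecture                                                     |
|----------------|------------------------------------------------------------------|
| `long_type`    | one complete 140–160 aa domain, often with a ~50 aa N-tail       |
| `short_type`   | domain lacking the conserved 31–32 aa C-terminal block           |
| `truncated`    | arthropod paralog of the long type with the C-block deleted      |
| `partial_only` | 1–4 free-standing copies of the 31–32 aa block (± motif ± 14 aa) |
| `multidomain`  | 70–140 aa p25alpha fragment(s) plus foreign domains (EFh, IQ, …) |
| `apicortin`    | partial p25alpha block combined with a DCX (doublecortin) domain |

The subfamilies have distinctive phyletic ranges across the eukaryotic
supergroups (Opisthokonta, Amoebozoa, Apusozoa, Archaeplastida,
Chromalveolata, Rhizaria, Excavata) and contrasting structural characters:
long-type and partial-domain proteins are predicted intrinsically
disordered, short-type and truncated ones ordered.

`tpppscan` implements this survey as a reproducible pipeline: a segmented
position-specific profile of the domain (N-tail, core, partial core,
extension), gapless profile scanning, motif and extension detection,
rule-based subfamily classification, supergroup × subfamily tabulation with
EST sub-counts, a charge–hydropathy disorder profiler with the conventional
0.5 threshold, neighbor-joining identity trees, reciprocal-best-hit
orthology, and a fully labelled synthetic-sequence generator so every stage
is testable without database downloads. Packaged fixture tables transcribe
the published truncated / multidomain / partial-domain censuses (metadata
only, no sequences).

### Scoring model

Profile columns are smoothed log-odds against a uniform background: the
score of residue *a* at column *i* built from *n* aligned sequences with
pseudocount *c* is

```
S(i, a) = log[(count(i, a) + c) / (n + 20 c)] − log(1/20)
```

A window's **normalized score** is its raw score divided by the maximum
attainable (sum of per-column maxima); hits are tiered `strong` (≥ 0.80),
`weak` (≥ 0.55) or `candidate` — the portable counterpart of the E-value
tiers used in database surveys. The disorder score maps the fold index
`f = 2.785⟨H⟩ − |⟨R⟩| − 1.151` (windowed Kyte–Doolittle hydropathy ⟨H⟩
rescaled to [0, 1]; windowed net charge ⟨R⟩ with K, R = +1, D, E = −1)
through a logistic centred at `f = 0 ↦ 0.5`.

All coordinates are 1-based and inclusive (`end − start + 1` = width).

## Worked example

```r
library(tpppscan)
library(dplyr)

model <- default_p25_model()
specs <- bind_rows(
  synth_spec("long_type",    n = 3, substitution_rate = 0.05),
  synth_spec("truncated",    n = 2, substitution_rate = 0.05),
  synth_spec("partial_only", n = 2, substitution_rate = 0.05),
  synth_spec("apicortin",    n = 1, substitution_rate = 0.05)
)
ds    <- generate_dataset(specs, model, seed = 20)
calls <- classify_proteins(ds$records, model, annotations = ds$annotations)
select(calls, id, species, label, n_p25_copies, n_partial_copies,
       has_extension, has_ntail)
#> # A tibble: 8 × 7
#>   id        species  label n_p25_copies n_partial_copies has_extension has_ntail
#>   <chr>     <chr>    <chr>        <int>            <int> <lgl>         <lgl>
#> 1 LONG_001  Homo sa… long…            1                1 TRUE          TRUE
#> 2 LONG_002  Homo sa… long…            1                1 TRUE          TRUE
#> 3 LONG_003  Homo sa… long…            1                1 TRUE          TRUE
#> 4 TRUNC_001 Drosoph… trun…            1                0 FALSE         FALSE
#> 5 TRUNC_002 Drosoph… trun…            1                0 FALSE         FALSE
#> 6 PART_001  Giardia… part…            0                4 TRUE          FALSE
#> 7 PART_002  Giardia… part…            0                1 TRUE          FALSE
#> 8 APICO_001 Toxopla… apic…            0                1 TRUE          FALSE
```

Every call was recovered correctly at 5% substitution noise: the long-type
records keep their one full domain (with N-tail and post-motif extension),
the truncated ones show a core without the partial block, `PART_001`
carries four free-standing partial copies, and the DCX annotation turns
`APICO_001` into an apicortin. The distribution table renders in the
censuses' "total (est)" style:

```r
tabulate_distribution(calls)
#> supergroup       group        long_type  short_type  truncated  partial_only  multidomain  apicortin
#> Opisthokonta     Arthropoda   .          .           2          .             .            .
#> Opisthokonta     Vertebrata   3          .           .          .             .            .
#> Chromalveolata   Alveolata    .          .           .          .             .            1
#> Excavata         Fornicata    .          .           .          2             .            .
#> Total                         3          .           2          2             .            1
```

Scanning one noisy long-type sequence shows the domain geometry the
classifier works from — a strong core hit after the 50-residue tail:

```r
scan_profile(ds$records$sequence[[1]], model, "core")
#> # A tibble: 1 × 6
#>   segment start   end score normalized_score tier
#> 1 core       51   169  110.            0.917 strong
glance(disorder_scores(ds$records$sequence[[1]]))
#> # A tibble: 1 × 6
#>   n_residues window threshold disordered_fraction n_disordered_regions longest_region
#> 1        214     21       0.5               0.425                    2             48
```

42% of the long-type protein is predicted disordered (the N-tail plus the
partial core and extension), while a short-type core profiles as fully
ordered — the subfamily contrast the survey predicts.

The packaged fixtures reproduce the published census cells directly:

```r
taxon_count(tabulate_distribution(fixture_calls("T2_truncated")),
            "Arthropoda", "truncated")   # 21 truncated arthropod TPPPs
glance(tabulate_distribution(fixture_calls("T3_multidomain")))$multidomain  # 18
```

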