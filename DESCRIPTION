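Package: tpppscan
Title: Domain-Architecture Classification and Phyletic Profiling of
    TPPP-Like Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying the TPPP (tubulin polymerization promoting
    protein) superfamily, whose members are defined by the p25alpha domain.
    Provides position-specific profile scanning for the long p25alpha domain,
    its conserved 31-32 residue C-terminal ("partial") block, the GXGXGXXGR
    Rossmann-like motif and the 14-residue post-motif extension; rule-based
    classification of proteins into the six architecture subfamilies
    (long-type, short-type, truncated, partial-only, multidomain, apicortin);
    tabulation of their phyletic distribution across eukaryotic supergroups
    and megagroups; a charge-hydropathy intrinsic-disorder profiler with the
    conventional 0.5 threshold; neighbor-joining trees from alignment
    identity distances; and a labelled synthetic-sequence generator that
    reproduces the subfamily architectures so that every stage of the
    pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
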