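Package: lingodx
Title: Multilingual Benchmarking of Ranked Differential Diagnosis from
    Large Language Models
Version: 0.1.0
Authors@R:
    person("Lingodx", "Developers", email = "lingodx@example.org",
           role = c("aut", "cre"))
Description: A pipeline for benchmarking the rare-disease differential
    diagnosis performance of large language models across languages. Renders
    GA4GH Phenopackets into narrative zero-shot prompts in ten languages via
    ontology translation tables and per-language template packs, dispatches
    prompts to a pluggable model backend (including a deterministic mock
    backend for testing), grounds free-text candidate diagnoses to a disease
    ontology with subtype-equivalence rollup, and aggregates Top-N ranked
    accuracy tables together with cross-language Kruskal-Wallis statistics.
    Ships synthetic mini-ontologies, translation tables, phenopacket corpora
    and template packs so the full pipeline runs with no downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringi,
    digest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
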