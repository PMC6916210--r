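Package: dlcpareto
Title: Pareto-Optimal Gene Tree Reconciliation Landscapes under the
    Duplication-Loss-Coalescence Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the full set of Pareto-optimal event counts
    (duplications, losses, deep coalescences) over all maximum-parsimony
    reconciliations of a rooted binary gene tree with a rooted binary
    species tree under the duplication-loss-coalescence (DLC) model,
    together with the number of optimal reconciliations per count and the
    frequency of every constituent event.  Partitions a two-dimensional
    duplication/loss event-cost rectangle (coalescence cost normalized to
    one) into equivalence regions with exact rational geometry, and
    reports per-event region and consensus support.  Includes a
    brute-force reconciliation enumerator for validation on small
    instances and a synthetic instance generator.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
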