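Package: varstab
Title: Structural Triage of Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis core for structural triage of protein missense
    variants. Given a protein sequence, a single amino-acid substitution, a
    manifest of candidate structural models and tabular annotations, the
    package selects the most suitable model under a quality-flagged
    preference hierarchy, estimates the folding free-energy change (ddG)
    both with a fast solvent-accessibility based estimator and with a
    deterministic neighbourhood repack protocol over an empirical pairwise
    energy, annotates the structural neighbourhood with population and
    clinical variants, post-translational modifications and sequence
    features, detects gained and lost short linear motifs, and provides a
    benchmarking metric suite and cohort survey statistics. A synthetic
    fixture generator produces structures, annotation tables and benchmark
    datasets with known ground truth so that every step runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
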