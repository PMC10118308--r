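Package: quatfun
Title: Assessing the Functional Contribution of Quaternary Structure in
    Homodimers
Version: 0.1.0
Authors@R:
    person("Quatfun", "Maintainers", email = "maintainers@quatfun.org",
           role = c("aut", "cre"))
Description: Tools to decide whether the quaternary structure of a homodimer
    contributes to its biochemical function. The package annotates biounit
    structures (interface, solvent-accessible surface and ligand-binding
    residues; multichain vs single-chain binding sites), computes
    coevolution-based Z statistics from pairwise evolutionary coupling
    scores, an interface-conservation delta, and a coupling-dynamics R^2
    statistic from an elastic-network normal-mode model, and combines the
    three statistics into per-complex non-functionality flags with
    Benjamini-Hochberg correction, interface-size strata, Venn overlaps
    against simulated random expectations, and a covariate-adjusted
    (ANCOVA) binding-site-type analysis. Companion modules compare the
    amino-acid composition of interfaces with missense-variant spectra and
    run knockout flux-variability analysis on small metabolic models. A
    synthetic-data generator plants parameterised ground truth in every
    input so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
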