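Package: msiith
Title: Intra-Tumor Heterogeneity Analysis for MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("MSI", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying intra-tumor heterogeneity
    from MALDI mass spectrometry imaging (MSI) of tissue sections. Provides
    spectra preprocessing (mass-axis unification, baseline subtraction,
    outlier spectrum detection, peak alignment, TIC normalization), Gaussian
    mixture decomposition of the cohort mean spectrum into spectral
    components, divisive iterative k-means (DivIK) segmentation with
    region-driven feature selection, per-region heterogeneity metrics
    (pairwise spectral similarity, cluster counts, Simpson's diversity
    index), nonparametric group-level inference (Wilcoxon rank-sum,
    Kruskal-Wallis with Conover post hoc, eta-squared, rank effect sizes),
    Cohen's-d screening of discriminatory components, and peptide/protein
    annotation by mass-tolerance matching. A synthetic cohort generator with
    planted ground truth makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
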