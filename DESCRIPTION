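Package: airspacer
Title: Airspace Micromechanics Quantification on Tomographic Lung Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies terminal-airspace number and dimension on
    high-resolution tomographic lung slices acquired during decremental-PEEP
    maneuvers. Provides a seeded synthetic phantom generator emulating
    ARDS-like (balloon) and healthy-like (derecruitment) deflation mechanisms
    with ground-truth label maps; multi-scale black top-hat enhancement with
    h-maxima peak counting and watershed-style airspace delineation;
    concentric pleural-distance regions of interest (subpleural, mantellar,
    core); airspace density (ASnum) and mean airspace extension (ASdim)
    metrics; and the statistical layer (pooled OLS regression of each metric
    on applied PEEP, extra-sum-of-squares F-tests between regressions, exact
    Wilcoxon signed-rank test, Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
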