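Package: isletmt
Title: Automated 3D Quantification of Beta-Cell Proliferation in Human
    Islet Microtissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of multi-channel 3D confocal stacks of
    reaggregated human islet microtissues. Implements a four-step
    segmentation algorithm (Otsu-based spheroid detection, dynamic-threshold
    nuclear and marker segmentation, label colocalization) to count total
    cells (DAPI), beta cells (NKX6.1), and proliferating cells (EdU) per
    microtissue, together with per-microtissue metrics (beta-cell fraction,
    proliferation percentages, mean NKX6.1 intensity, spheroid volume) and
    the accompanying dose-response statistics: ROUT outlier removal,
    one-way ANOVA with Dunnett's many-to-one comparisons, Student's t-test,
    and glucose-stimulated insulin secretion endpoint summaries. A bundled
    synthetic-data generator renders anisotropic confocal stacks with
    per-nucleus ground truth and simulated functional readouts for
    validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    mvtnorm,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
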