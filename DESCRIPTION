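Package: mesovasc
Title: Mesoscopic Cerebrovascular Function Quantification for Awake-Mouse
    Optical Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification chain for awake-mouse mesoscopic cerebrovascular
    imaging studies. Reads interleaved trichromatic widefield camera stacks and
    demultiplexes them into GCaMP fluorescence and haemoglobin-weighted optical
    intrinsic signal (OIS) channels; preprocesses movies by spatial binning,
    Fourier-based sub-pixel rigid registration and illumination-drift
    regression; quantifies whisker-evoked neurovascular coupling (dF/F0
    activation maps, greedy top-k barrel ROI, peak GCaMP and OIS-BOLD
    responses and their ratio) and hypercapnic cerebrovascular reactivity
    (K-means large-vessel removal, tissue dR/R0 time series, peak CO2
    responses); measures single-vessel diameters by full-width-at-half-maximum
    of cross-sectional intensity profiles and per-cent dilation across a CO2
    challenge; quantifies cerebral amyloid angiopathy coverage and tissue
    plaque volume from two-photon z-stacks; and fits the cohort-level
    statistics (linear mixed-effects models with mouse random intercepts,
    Johnson-Neyman conditional-effect regions, median-split group contrasts
    with Holm adjustment). A synthetic-data generator produces imaging
    sessions, vessel movies, two-photon volumes and longitudinal cohorts with
    known ground truth so the full chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    nlme,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
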