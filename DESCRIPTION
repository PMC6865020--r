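Package: hydrostate
Title: Ecohydrological State-Space Diagnostics and Change Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps gridded annual water and energy fluxes (precipitation,
    net radiation, evapotranspiration) into the Budyko-style (U, W) state
    space of relative excess energy and relative excess water, detects
    significant two-period change against interannual variability, and
    attributes per-pixel displacements to external (climate) versus
    internal (anthropogenic) causes via orthogonal projection onto the
    dryness diagonals. Includes greenness-trend and nighttime-light urban
    stratification, connected-component city detection with
    latitude-weighted areas, state-space frequency densities, a seeded
    synthetic-landscape generator with ground-truth labels, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
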