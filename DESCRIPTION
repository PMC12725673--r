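Package: vccr
Title: Virtual Catch Change Reconstruction from Fisher Interview Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs decadal catch and effort trends of data-poor
    artisanal fisheries from structured local-ecological-knowledge (LEK)
    interviews. Converts per-decade categorical trend scores with
    fisher-assigned percentages into per-fisher Virtual Catch Change (VCC)
    trajectories with shifting-baseline correction, aggregates them into
    decadal cohort means with cubic trend fits, rasterizes fisher-drawn
    fishing-ground polygons into normalized effort and VCC surfaces on a
    regular lon/lat grid, summarises centroid-to-port geodesic distances
    per decade, and computes Yamane finite-population sample sizes for
    survey design. A synthetic survey generator with recorded ground truth
    supports end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    jsonlite,
    geosphere,
    sp,
    ggplot2,
    generics,
    digest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
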