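Package: streamclass
Title: Multi-Layered Habitat Classification of Stream Reach Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns six habitat-layer classes (size, gradient, hydrology,
    temperature, network bifurcation, valley confinement) to every reach of
    an NHDPlus-style stream network. Provides a reach-network data model with
    topology validation, Strahler ordering and upstream accumulation;
    discharge-based size thresholds from order medians; tributary-junction
    and divergence coding with split-reach correction; Ward clustering of
    gage hydrologic signatures with random-forest class extrapolation and
    vote-fraction probabilities; reference-site screening and summer
    temperature prediction with Fisher-Jenks optimal partitioning; a
    simplified flood-height valley-bottom delineation and confinement rule
    engine; and seeded synthetic generators (dendritic networks with
    divergences and map-boundary splits, clustered gage panels, temperature
    sites, valley-bottom inputs) so the whole pipeline runs with no external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
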