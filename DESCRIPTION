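Package: occuclim
Title: Occurrence-Record Cleaning and Semiquantitative Climatic
    Characterization of Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for rule-based cleaning of multi-source species
    occurrence databases (replicate removal, coordinate-precision and
    coastal-distance filters, cultivated-record flagging, native-range
    filtering against TDWG botanical countries), for building categorical
    bioclimatic regionalizations of a study grid (latitudinal zonation,
    Holdridge biotemperature life zones, aggregated Koppen-Geiger main
    classes, simplified ecoregion biomes, pass-through environmental
    stratifications), and for deriving per-taxon climatic preference
    profiles, sampling-effort grids with Jenks natural-breaks hotspot
    categories, temporal accumulation series, and AOO/EOO range-size
    metrics.  A seeded synthetic-data generator with planted,
    class-disjoint errors makes every pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    geosphere,
    sp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
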