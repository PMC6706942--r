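Package: piscape
Title: Proteome Isoelectric-Point Landscapes and Habitat Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-protein net charge and isoelectric points (pI)
    under a Henderson-Hasselbalch ionization model with selectable pKa
    sets, turns proteome pI lists into binned relative-frequency spectra
    with acid/neutral/basic aggregates, and compares pI profiles across
    aquatic habitats (freshwater, brackish, marine, halophile) with
    Bray-Curtis distances, one-way PERMANOVA, principal component
    analysis, and a nearest-centroid habitat classifier. Includes
    reciprocal-best-hit proteome comparison (average amino-acid identity,
    percentage of conserved proteins, core/flexible partition), a
    hydropathy-based localization heuristic with an annotation import
    path, and a seeded synthetic proteome generator that emulates the
    marine acidic shift and freshwater basic shift in amino-acid
    composition, so the full analysis runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
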