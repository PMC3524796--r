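Package: arborscape
Title: Morphometry and Classification of Cutaneous Sensory Afferent Arbors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative analysis of traced cutaneous sensory
    afferent arbors in hairy skin. Reads and writes SWC-style neuron
    reconstructions and hair-follicle map tables, corrects Z coordinates for
    clearing-induced tissue shrinkage, and computes per-arbor morphometrics:
    total axon length, branch points, convex-hull receptive-field area,
    depth stratification and two-tier decomposition. Detects terminal ending
    specializations (lanceolate, circumferential, thick, free), assigns them
    to hair follicles, and derives innervation statistics (innervation
    index, fraction of follicles innervated, coverage factors) together with
    circular statistics of C-shaped lanceolate ending orientation relative
    to the follicle axis. A rule-based classifier assigns each arbor one of
    ten morphologic types, and a synthetic-data generator produces follicle
    lattices and ground-truthed arbors of every type for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
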