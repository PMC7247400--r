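Package: ddrmap
Title: Joint Dose-Time Modelling of Dynamic Dose-Responsive Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated dose-time analysis of toxicogenomics log
    fold-change data. Fits constant to third-order polynomial response
    surfaces over the joint dose-time space for every gene, selects the
    optimal order by nested-model F-tests with a Benjamini-Hochberg gate,
    predicts a dense dose-time effect map with its analytic gradient
    field, segments monotone dose-responsive areas, assigns joint
    dose-time point-of-departure labels under four strategies, quantifies
    the relative influence of dose and time from the gradient direction,
    and performs gene-set overrepresentation analysis of the resulting
    gene groups. Includes a synthetic-data generator emulating a
    three-dose, four-time in vivo design with pairwise treated-control
    log fold-changes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
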