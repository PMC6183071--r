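Package: abasicsirna
Title: Design of Off-Target-Free siRNAs with an Abasic Pivot
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing small interfering RNAs that carry an abasic
    spacer at guide position 6 (the pivot), a modification that abolishes
    microRNA-like off-target repression. Implements a nearest-neighbor RNA:RNA
    duplex free-energy engine for short perfectly complementary regions under
    an N-padding convention, enumeration of transitional-nucleation 4-mers and
    selection of the potent set by a free-energy window, a full target-site
    filter cascade over coding sequences with mask avoidance and
    transcriptome-uniqueness checking, screening-data statistics (strand-bias
    selection, frequency-weighted family energies, energy-normalized
    correlation, energy-binned activity), four-parameter logistic IC50
    fitting, cumulative-fraction (ECDF and Kolmogorov-Smirnov) comparisons,
    and deterministic synthetic-data generators that exercise the whole
    pipeline without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
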