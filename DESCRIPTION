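Package: phasevar
Title: Phase Variability Decomposition for Episodically Switching Rhythmic Motor Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the sources of intersegmental phase variability in
    rhythmic motor systems that alternate between two coordination states, such
    as the bilaterally symmetric leech heartbeat system. Converts spike trains
    and constriction traces into per-cycle intersegmental phase differences,
    segments them into coordination episodes and switch cycles, and decomposes
    phase variability into cycle-to-cycle, repetition, bilateral, and population
    components using circular statistics (mean resultant length, angular
    variance), bootstrap confidence intervals, and scrambling (permutation-style)
    null distributions. Also estimates synaptic strength by spike-triggered
    averaging of voltage-clamp currents, with conductance conversion and
    bilateral proportional-strength comparisons. A hierarchical synthetic-data
    generator with known ground truth supports validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
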