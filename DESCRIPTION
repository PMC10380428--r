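Package: volatax
Title: Chemotaxonomic Species Identification from Volatile Headspace Profiles
Version: 0.1.0
Authors@R:
    person("Volatax", "Developers", email = "volatax@example.org", role = c("aut", "cre"))
Description: Tools to identify species (originally aphids) from aligned GC-MS
    headspace peak tables using hierarchical rounds of canonical analysis of
    principal coordinates (CAP). Each round runs a constrained ordination of a
    chosen dissimilarity against a-priori groups, measures separation quality by
    leave-one-out allocation and permutation tests, and overlays compound
    vectors whose squared lengths select essential and semi-essential
    biomarkers. Biomarkers are assembled into a dichotomous identification key
    against which unknown volatile profiles can be matched. Includes a
    synthetic-data generator that emulates the statistical structure of
    multi-species volatilomes (species-specific markers, a widely shared alarm
    pheromone, host-plant compounds, log-normal replicate noise and detection
    dropout) for testing and marker-recovery experiments, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
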