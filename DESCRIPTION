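Package: clustersim
Title: Simulation of Cluster-Based, Computer-Assisted Image Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the human-in-the-loop annotation workflow in which deep
    image representations are clustered, candidate clusters are validated
    against gold-standard labels, and accepted clusters are grown by an
    exponential/binary/linear search over distance-ranked batches of
    unclustered objects, while every virtual user interaction ("click") is
    recorded. Implements two partial clustering algorithms tailored to this
    workflow, shrunken k-means and partially labeled k-means (a constrained
    Lloyd iteration that freezes validated labels, honours cannot-link
    rejections and trims a noise fraction from centroid updates), plus an
    adapter for density-based HDBSCAN* candidate generation. Includes a
    synthetic embedding generator with controllable class separation, class
    imbalance, diffuse noise and sub-class structure, the evaluation metrics
    of the workflow (annotation efficiency in objects per click,
    completeness, per-cluster precision, nearest-centroid-classifier F1),
    and a reproducible experiment runner with plain-text I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with scikit-learn (>= 1.3), required
    only for the HDBSCAN* candidate generator.
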