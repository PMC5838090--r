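Package: spraymode
Title: Spray-Mode Analysis of Electrospray Droplet Delivery from High-Speed Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the spray mode of an electrospray (electrohydrodynamic
    atomization) delivery device from high-speed video of the droplet stream.
    Detects droplet images frame by frame, links them into trajectories including
    in-flight splitting events, qualifies trajectories by traversal of an axial
    region of interest and by focal range, estimates each droplet's volume under a
    rotational-symmetry (ellipsoid-of-revolution) model and its impact velocity
    from the last two tracked frames, and clusters droplets in (volume, velocity)
    space by k-means with silhouette-guided selection of the number of groups,
    reporting per-group centroids, group volumes and fractional volume
    contributions. A synthetic spray-video generator with full ground truth makes
    every stage verifiable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    tiff,
    png,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
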