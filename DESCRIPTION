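Package: springgeo
Title: Latent Geometry of Biological Networks via Spring-Model Stiffness
Version: 0.1.0
Authors@R: person("springgeo", "developers", role = c("aut", "cre"),
    email = "springgeo@example.org")
Description: Models a gene/protein interaction network as a system of
    masses and springs, derives an all-pairs spring-stiffness matrix from
    the nullspace of the mass-weighted incidence matrix, converts it to a
    dissimilarity matrix, embeds the network into Euclidean, hyperbolic
    (Poincare ball) and spherical metric spaces, selects the latent
    geometry with minimum embedding stress, and clusters hyperbolic radial
    coordinates to identify candidate driver nodes of the network
    dynamics.  Includes parsers for SIF interaction tables, synthetic
    planted-geometry generators, a spectral-clustering baseline, and a
    reproducible command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
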