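Package: iccbem
Title: Induced-Charge Boundary-Element Electrostatics for Nano-Scale
    Dielectric Systems
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the polarization charge induced on sharp dielectric
    boundaries by discrete point charges (the primitive model of
    electrolytes), using a collocation boundary-element method. Two
    solution strategies are provided: the direct induced-charge
    computation (ICC), which assembles and factors a dense geometric
    coupling matrix once and reuses it for arbitrary charge
    configurations, and an iterative Jacobi-style refinement (ITER) with
    a per-tile relative-update stopping rule. Includes analytic tile
    generators for spheres and axisymmetric membrane-channel profiles,
    evaluation of total and reaction potentials, a mandatory Gauss's-law
    audit, a Legendre-series reference solution for a point charge in a
    dielectric sphere, benchmark scenarios (dielectric sphere, toy ion
    channel with dipole rings), and a command-line interface driven by
    structured JSON configuration files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
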