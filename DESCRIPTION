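Package: fkppfronts
Title: Traveling Waves and Self-Organized Fronts in an Active/Inactive
    Particle Growth Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and analyses traveling-wave solutions of an
    FKPP-type reaction-diffusion system for densities of active (branching,
    diffusing) and inactive (static) particles, a continuum description of
    branching morphogenesis. Provides the closed-form quantities of the wave
    problem (critical inactive density, decay rates, limit map, turning-point
    identities), heteroclinic orbit construction by shooting from the
    one-dimensional unstable manifold, invariant trapping triangles for the
    reduced phase plane, a method-of-lines simulator of the full PDE with
    front tracking, a discretized spectral-stability analysis of the
    linearization around a wave in exponentially weighted spaces, and
    synthetic scenario generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    pracma,
    tibble,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
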