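Package: uromt
Title: Unbalanced Regularized Optimal Mass Transport for Dynamic Density Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a time-varying velocity field and a relative source to a
    sequence of nonnegative 3D density images under an
    advection-diffusion-source equation, by Gauss-Newton minimization of a
    kinetic-energy plus Fisher-Rao plus end-point-mismatch cost with
    matrix-free Hessian-vector products and preconditioned conjugate
    gradients. Includes Eulerian speed and relative-source maps with time
    averaging, Lagrangian pathline, speed-line, Peclet-line and velocity
    flux-vector post-processing, a Gaussian-sphere synthetic benchmark
    generator, NIfTI volume input/output, legacy VTK polydata export and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
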