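Package: pavemech
Title: Mechanics of Pavement-Cell Walls and Microtubule Readouts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates mechanical stress in the turgid outer wall of leaf
    epidermal (pavement) cells with a nonlinear finite-element membrane
    model (Saint Venant-Kirchhoff matrix plus transversely isotropic
    cellulose-fiber reinforcement, anticlinal-wall beam elements, follower
    turgor pressure, stress-to-fiber feedback, ablation and plate-compression
    perturbations), and quantifies the cytoskeletal readouts used alongside
    such models: nematic/texture-tensor anisotropy scores of filament images,
    Hertz-Sneddon and DMT force-curve fitting for apparent-modulus maps, and
    severing/crossover event statistics. Ships synthetic-data generators
    (jigsaw cell geometries, oriented filament textures with prescribed
    nematic order, force-curve grids, Poisson severing series) so every stage
    is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
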