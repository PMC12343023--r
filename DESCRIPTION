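Package: moldiff
Title: SE(3)-Equivariant Latent Diffusion for 3D Molecule Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative modelling of small 3D molecules with a latent
    denoising diffusion probabilistic model whose autoencoder and denoiser
    are geometry-complete, SE(3)-equivariant message-passing networks over
    fully connected molecular graphs. Per-pair local orthonormal frames
    built from atom coordinates scalarize vector features without
    information loss and make the model chirality-aware (equivariant to
    rotations and translations but not to reflections). Includes molecule
    I/O (XYZ, SDF V2000), a synthetic toy-molecule generator with
    idealized covalent geometry, joint training of autoencoder and
    denoiser, ancestral sampling with an empirical molecule-size prior,
    optional property-conditional generation, and valence-based sample
    quality metrics (atom/molecule stability, validity, uniqueness).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'autodiff.R'
    'molgraph.R'
    'utils.R'
    'gcpnet.R'
    'autoencoder.R'
    'evaluation.R'
    'diffusion.R'
    'train.R'
    'cli.R'
    'moldiff-package.R'
    'molgraph-io.R'
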