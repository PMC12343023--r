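# moldiff

SE(3)-equivariant **latent diffusion** for generating small 3D molecules,
with the valence-based sample-quality metrics used to judge them.

## Who this is for

Researchers in generative chemistry who want a complete, CPU-scale,
dependency-light reference implementation of the geometry-complete latent
diffusion recipe: an equivariant autoencoder compressing molecules
`G = (x, h)` (coordinates + one-hot types/charges) into latent states
`z = (z_x, z_h)`, a denoising diffusion model trained in that latent
space, ancestral sampling with an empirical molecule-size prior `p(N)`,
and distance-based bond inference feeding atom/molecule stability,
validity and uniqueness metrics.

## The model in brief

Both networks are stacks of geometry-complete perceptron convolutions on
the fully connected molecular graph. Per ordered atom pair a local
orthonormal frame

    a_ij = (x_i - x_j)/||x_i - x_j||,  b_ij = (x_i x x_j)/||x_i x x_j||,  c_ij = a_ij x b_ij

scalarizes vector features losslessly; because `b_ij` is a pseudovector,
mirror images produce different messages — the model is equivariant to
rotations/translations but sensitive to chirality. The diffusion runs the
standard DDPM forward process `q(z_t | z_0) = N(sqrt(ab_t) z_0, (1-ab_t) I)`
on the zero centre-of-mass subspace and learns a noise-prediction network
`eps_hat(z_t, t)`; sampling applies

    z_{t-1} = (z_t - (1-a_t)/sqrt(1-ab_t) * eps_hat) / sqrt(a_t) + sigma_t * eps

with a deterministic final step. See the vignette
(`vignettes/geometry-complete-latent-diffusion.Rmd`) for assumptions,
parameters and numerical choices.

## Worked example

```r
library(moldiff)

# idealized toy molecules: 8 templates over H/C/N/O/F
mols <- generateToyDataset(50, seed = 3)
atomCountDistribution(mols)
#> AtomCountDistribution p(N) on { 2, 3, 4, 5, 6, 8 }
#>   probabilities: 0.100, 0.120, 0.280, 0.100, 0.340, 0.060

evaluateSamples(mols)            # zero jitter -> ideal geometry
#> StabilityReport over 50 molecules
#>   atom stability:      100.0%
#>   molecule stability:  100.0%
#>   validity:            100.0%
#>   valid and unique:    16.0%
```

The size distribution is the empirical histogram the sampler will draw
molecule sizes from; the report says every atom has a chemically correct
valence (each of the 8 distinct templates appears once among the unique
molecules, so 8/50 = 16% are valid *and* unique — the rest are duplicates
of the same small library, as expected).

Training the full model at desk scale (about 7 CPU-minutes):

```r
mols  <- generateToyDataset(500, seed = 1)
sch   <- makeSchedule(100)
ae    <- newAutoencoder(dH = 32, m = 4, dMsg = 32, seed = 2)
ae    <- trainAutoencoder(mols, ae, steps = 600, seed = 1)$ae
dn    <- newDenoiser(kLatent = 3, nLayers = 4, dH = 32, m = 4, dMsg = 32, seed = 3)
dn    <- trainDenoiser(mols, ae, dn, sch, steps = c(3000, 2000),
                       lr = c(2e-3, 5e-4), seed = 4)$denoiser
model <- new("LatentDiffusionModel", autoencoder = ae, denoiser = dn, schedule = sch,
             sizeDist = atomCountDistribution(mols), conditionNorm = numeric(0))
evaluateSamples(sampleMolecules(model, 200, seed = 10))
#> StabilityReport over 200 molecules
#>   atom stability:      86.3%
#>   molecule stability:  54.0%
#>   validity:            73.5%
#>   valid and unique:    21.0%
```

About six in seven generated atoms carry a correct valence and over half
of the molecules are entirely stable — on a model trained from scratch on
a CPU in minutes.

## Command line

A thin wrapper over the same functions ships in `inst/exec/moldiff`:

```sh
moldiff make-toy --n 500 --seed 1 --out toy.sdf
moldiff train    --config config.yaml
moldiff sample   --checkpoint out/checkpoint.rds --n 200 --seed 7 --out samples.xyz
moldiff evaluate --samples samples.xyz --out report.txt
```

Configs are YAML (`readRunConfig` documents the keys); molecule I/O is XYZ
and SDF V2000 (SDF preserves formal charges and an optional scalar
property used for conditional generation).

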