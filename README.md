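# tsengdeblur

Non-blind restoration of 2-D grayscale images — CT slices are the motivating
case — that have been degraded by **known linear motion blur plus additive
noise**. The degradation model is

    y = D x + η

where `x` is the clean image, `D` convolves with a motion point spread
function (PSF), and `η` is Gaussian or Poisson noise. The package recovers
`x` by solving the ℓ1-regularised least-squares problem

    min_x  ½‖D x − y‖² + μ‖x‖₁

with a **forward-backward-forward (Tseng) splitting** iteration. Writing
`f(x) = ½‖D x − y‖²` (so `∇f(x) = Dᵀ(D x − y)`), each iteration performs a
gradient step, a proximal (soft-thresholding) step, and a second gradient
correction:

    w_k     = (I + λμ ∂g)⁻¹ (x_k − λ ∇f(x_k))
    x_{k+1} = w_k − λ (∇f(w_k) − ∇f(x_k))

which converges to a minimiser whenever `λ < 1/L`, `L = ‖D‖²` (`L ≤ 1` for a
unit-sum PSF under circular boundaries). Besides the solver the package
provides:

- an anti-aliased **motion-PSF generator** (`make_motion_psf`), defined as
  the exact area-weighted rasterisation of a unit-width motion segment;
- the blur operator and its **exact adjoint** (`apply_blur`, `adjoint_blur`)
  under circular (FFT-based) or reflective boundaries;
- the **degradation simulator** (`degrade`) with seeded Gaussian/Poisson
  noise;
- restoration-quality **metrics** `ssim` (single-window structural
  similarity), `isnr` and `snr` (decibel forms);
- procedural **phantoms** (`generate_phantom`): a chest-CT-like slice, a
  classic-head-style ellipse phantom, sparse spots, and a flat field;
- a **CLI** (`inst/cli/tsengdeblur`) with `phantom`, `degrade`, `restore`,
  `evaluate` and `demo` subcommands, and `run_experiment()` for the full
  degrade → restore → evaluate pipeline with reproducible artifacts.

## Worked example

```r
library(tsengdeblur)

res <- run_experiment(experiment_config(
  phantom     = phantom_spec(size = 64, kind = "chest", seed = 1),
  degradation = degradation_spec(psf_length = 15, psf_angle = 45,
                                 noise_family = "gaussian",
                                 noise_level = 1e-3, seed = 2),
  solver      = solver_config(step_size = 0.9, reg_weight = 0.005,
                              max_iters = 150),
  out_dir = "demo", image_id = "chest64"))
print(res$metrics)
ssim(res$observation$observed, res$clean)   # degraded-vs-clean SSIM
```

prints (progress lines omitted):

```
SSIM 0.9132, ISNR 2.961 dB, SNR 9.758 dB
[1] 0.7668
```

Read: blurring with a 15-pixel motion kernel at 45° plus variance-0.001
Gaussian noise drops the phantom's SSIM against the clean image to 0.767;
150 solver iterations raise it to 0.913 and recover 2.96 dB of
signal-to-noise ratio relative to the degraded observation (`ISNR > 0`
means the estimate is closer to the truth than the observation was). The
output directory receives the clean/degraded/restored images, the PSF, the
per-iteration trace, a metrics CSV row, and a manifest of every parameter
and seed — rerunning the same configuration reproduces all of them byte for
byte.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/tsengdeblur demo --size 64 --seed 1 --out demo_dir
```

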