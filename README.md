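# iterFBP

Iterative filtered back-projection (FBP) reconstruction for
parallel-beam computed tomography, in R.

CT reconstruction from a sinogram — the stack of line-integral
projections $p_i(t)$ over scanning angles $\theta_i$ — is classically
done by FBP: ramp-filter every projection row in the frequency domain
and back-project,

$$\hat f(n,m) \;=\; \frac{\pi}{K}\sum_{i=1}^{K}
q_i\!\left(n\cos\theta_i + m\sin\theta_i\right),
\qquad
q_i \;=\; \mathrm{IDFT}\!\left[\mathrm{DFT}(p_i)\cdot|k/N|\right].$$

Discretisation (finite detector bins, finite angles, interpolation)
leaves aliasing error in $\hat f$.  This package implements, alongside
classic FBP, an iterative correction: the reconstruction is reprojected
along the original angles, the residual $\Delta p = p - \hat p$ against
the measured data is filtered row-wise with a short symmetric
deconvolution filter $F$ — designed as the least-squares solution of

$$\min_F \;\lVert h_n \otimes F - \delta \rVert_2^2,$$

where $h_n$ is the $2n{+}1$-tap spatial form of the ramp filter — and
the filtered residual is itself reconstructed by FBP and added to the
image.  The loop is driven by the reprojection mean-squared residual
$s = \frac{1}{LK}\sum_i \lVert \hat p_i - p_i\rVert_2^2$ and returns
the best-$s$ iterate.

The package is aimed at people studying reconstruction algorithms for
straight-ray tomography (X-ray CT, synchrotron imaging): it provides
the Shepp-Logan head phantom at arbitrary size, a mass-conserving
sub-pixel-splitting projector with its exact adjoint, the ramp-kernel
analytics ($\beta_N$, $h_n$), the filter design, the correction loop,
SIRT/SART/MAP-EM reference reconstructors, MSE/UQI/mutual-information
quality metrics, flat-/dark-field log normalisation for raw scans, and
TIFF/CSV I/O plus a small command-line front end (`ctrecon`).

## Worked example

```r
library(iterFBP)

ph  <- headPhantom(128)                       # modified Shepp-Logan, [0, 1]
sg  <- forwardProject(ph, seq(0, 179, by = 1))
cfg <- reconConfig(128, maxIterations = 2)

classic <- fbpReconstruct(sg, cfg)
fit     <- iterateFBP(sg, cfg)

fit$log
#>   iteration         s
#> 1         0 0.2944668
#> 2         1 0.2112280
#> 3         2 0.1687367

imageMSE(classic, ph); uqi(classic, ph)
#> [1] 0.003829539
#> [1] 0.9516465
imageMSE(fit$image, ph); uqi(fit$image, ph)
#> [1] 0.002820017
#> [1] 0.9659026

designFilter(rampKernel(5, 128))
#> CorrectionFilter, 11 taps (sum 2.0000), design residual 0.155:
#>  [1] 0.0321 0.0716 0.1231 0.1840 0.3078 0.5627 0.3078 0.1840 0.1231 0.0716
#> [11] 0.0321
```

The iteration log shows the reprojection residual `s` falling from
0.294 (classic FBP, iteration 0) over two correction iterations, while
the image-domain MSE against the phantom drops by ~26% and UQI rises
from 0.952 to 0.966.  The printed filter is the normalised (tap sum 2)
11-tap deconvolution filter for the ramp kernel `h_5` at DFT length
128.

The same operations are scriptable from a shell:

```sh
ctrecon simulate --size 128 --step 1 --out /tmp/run
ctrecon reconstruct --method ifbp --iters 2 --size 128 \
        --sinogram /tmp/run_sino.tif --out /tmp/rec.tif
ctrecon metrics --ref /tmp/run_phantom.tif --test /tmp/rec.tif
```

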