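# dyntexseg

Joint segmentation and tracking of image regions that differ by their
**motion patterns** rather than their intensities, for low-contrast
time-lapse microscopy. The motivating application is the *in vivo*
characterization of thrombus formation in the zebrafish caudal aorta
imaged by DIC microscopy, where the growing thrombus, the fast-flowing
blood in the vessel, and the quasi-static background are nearly
indistinguishable in any single frame but have sharply different temporal
dynamics. The pipeline yields the two biological read-outs of such
experiments: the **thrombus surface area (TSA)** over time and the
**time to attachment (TTA)** of the first blood cells.

## The model

Every pixel `x` carries a **dynamic-texture model**: the intensities
`y(t)` of the 5×5 patch around `x`, observed over a temporal window of
`τ+1` frames, are modelled by an order-`n` linear dynamical system

    z(t+1) = A z(t) + v(t),        v ~ N(0, Q)
    y(t) − ȳ = C z(t) + w(t),      w ~ N(0, R)

with `A ∈ R^{n×n}`, orthonormal `C ∈ R^{p×n}`, estimated in closed form
from the SVD of the mean-subtracted patch stack (`Ĉ = U`,
`Â = Ẑ₂ Ẑ₁†`). Models are compared by the **Martin distance** on the
column spaces of their observability matrices
`O = [Cᵀ, AᵀCᵀ, …, (A^{n−1})ᵀCᵀ]ᵀ`:

    d_M²(D₁, D₂) = −log ∏ᵢ cos² θᵢ,

the `θᵢ` being the principal angles between the two subspaces.

Segmentation into thrombus `Ω₁`, uncoagulated vessel `Ω₂`, and background
`Ω₃` minimizes a multiphase two-level-set energy

    E = α·E_ms + β·E_ed − γ·E_sp + ζ·E_top

* `E_ms` — motion-segmentation likelihood: per-region normal statistics
  on the dynamic-texture manifold, with the region mean taken either as a
  sampled **Fréchet mean** (exhaustive search over observed models) or by
  the **Doss** surrogate (weighted mean of squared distances to sampled
  region models), and boundary-confidence weights down-weighting patches
  that straddle region boundaries;
* `E_ed` — event-detection likelihood on the map
  `Δ(x) = d_M²(D_x^{t0}, D_x^t)` comparing each pixel's model against a
  reference window before the thrombus develops;
* `E_sp` — tubular shape prior: an "infinite rectangle" (centerline +
  radius) is refit to the vessel region at each iteration and pixels far
  from the band are penalized exponentially;
* `E_top` — topological prior penalizing the fourth sign class
  (inside the thrombus contour but outside the vessel contour).

The regions are the sign classes of two embedding functions `Φ₁, Φ₂`
evolved by diffusion-regularized gradient descent, alternating with
seeded resampling of the region statistics. A backward tracker propagates
the converged contours from the last temporal window through the
sequence (one active frame every `decimation` frames, shape-based
interpolation in between) and extracts the TSA series and the TTA.

Seeded generators build every kind of validation input: travelling-wave
LDS textures, multi-region scenes, temporally shifted event pairs,
intensity vessel phantoms with collateral branches, and growing-plug
sequences with exact ground truth.

## Worked example

```r
library(dyntexseg)

# a 64x64x75 scene: slow-wave disk (thrombus) inside a fast-wave square
# (vessel) on a near-static background, plus ground-truth labels
scene <- make_scene(disk_square_scene(T = 75, seed = 1))

cfg <- solver_config(alpha = 1, beta = 0, gamma = 0, zeta = 1.25,
                     n = 2, tau = 74, patch_side = 3, stride = 1,
                     n_samples = 40, mean_mode = "doss",
                     max_outer = 40, max_inner = 4, kappa = 0.4, seed = 1)

# far-off polygonal initial contours (vertices are (row, col) pairs)
polys <- list(vessel   = rbind(c(8, 14), c(10, 56), c(52, 58), c(56, 10)),
              thrombus = rbind(c(22, 20), c(24, 42), c(44, 40), c(40, 18)))

res <- segment(scene$sequence, c(1, 75), init = polys, config = cfg)
print(res)
rand_index(res$labels, scene$labels)
```

This prints:

```
dts_segmentation: converged

background     vessel   thrombus  forbidden
      2075       1763        258          0
```

and a Rand index of `0.909` against the generator's ground truth (the
true regions hold 2247, 1516 and 333 pixels; the residual error is the
±1-pixel ring of patches straddling region boundaries, whose models mix
two motion patterns). The Dice coefficients are `0.873` for the thrombus
and `0.956` for the vessel. Tracking works the same way, one level up:

```r
gp <- make_growing_plug_sequence(seed = 1)     # 96x128x300, onset at frame 120
tr <- track(gp$sequence, init = polys_for_plug, config = cfg_tracking,
            decimation = 10, window_lead = 10)
plot(tr, truth = gp$tsa_true)
tr$tta_s                                        # estimated attachment time (s)
```

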