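# tissuedeform

Vision-based recovery of soft-tissue deformation and tool–tissue interaction
forces from calibrated stereo microscope images.

During microsurgery, the forces a blunt instrument exerts on tissue are often
below the surgeon's haptic threshold (dissection forces under 0.3 N are
common), yet the tissue visibly deforms. `tissuedeform` turns a calibrated
stereo view of that deformation into a force estimate, with no added
hardware:

1. **Quasi-dense stereo reconstruction.** Affine-covariant elliptical regions
   are matched across the rectified pair by maximizing
   `M = |R_i ∩ R_j|/|R_i ∪ R_j| + min(c_i,c_j)/max(c_i,c_j)` subject to
   region overlap > 60 % and histogram-equalized NCC > 90 % on the epipolar
   band, then densified locally and propagated to neighboring features whose
   shape-from-shading surface normals `N = (p,q,−1)/√(p²+q²+1)` agree within
   1°. Matches are triangulated (`Z = f·b/d`) into a point cloud in mm.
2. **Deformation recovery.** Distinctive features are tracked over time on
   the left image (pyramidal Lucas–Kanade with NCC confidence) and
   re-triangulated per frame; each point's deformation is
   `D = ‖S_t − S_ref‖` against a reference reconstruction. Points with 3D
   data but no reliable track are mapped through a 3D thin-plate spline
   (kernel `U(r) = r`) anchored on the stable features and confirmed against
   the current frame's reconstruction.
3. **Force estimation.** The displacement field around the (occluded) tool
   tip is fitted with a Gaussian `D(u) = A·exp(−‖u−c‖²/2σ²) + b`; the peak
   `A + b` is the tool-tip displacement, converted to newtons through a
   calibrated quadratic force–displacement model `F = a₂d² + a₁d + a₀`.

A synthetic-scene module renders fully ground-truthed stereo sequences
(textured deformable surface, known rig, scheduled Gaussian indentation, tool
occluder, force labels), so the entire pipeline is testable offline.

The package is tidyverse-native: feature sets, match tables, point clouds,
deformation fields and force reports are tibbles; fitted models have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## Worked example

Simulate a deforming scene, reconstruct it, recover deformation and estimate
the tool force:

```r
library(tissuedeform)

scene  <- make_scene(image_size = c(320, 240), n_frames = 5,
                     max_indent_mm = 10, seed = 7)
frames <- lapply(1:5, function(f) render_stereo(scene, f))
rect   <- rectify_pair(scene$rig, frames[[1]]$img_L, frames[[1]]$img_R)$rig

td <- track_deformation(rect,
                        lapply(frames, `[[`, "img_L"),
                        lapply(frames, `[[`, "img_R"))

# deformation field at the final frame (scheduled indentation: 10 mm)
field <- td$fields[[5]]
summary(field$D[field$stable])

est <- estimate_force_from_field(field, scene$material,
                                 occlusion = list(center = scene$indent_center,
                                                  radius = 4))
est
ground_truth_force(scene, 5)
```

Output (as printed by the code above):

```
   Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
 0.0609  0.6074  0.9436  1.0043  1.2622  6.9471

# A tibble: 1 × 6
  peak_mm force_N extrapolated  center_x center_y sigma_mm
    <dbl>   <dbl> <lgl>            <dbl>    <dbl>    <dbl>
1    10.1    1.22 FALSE        0.0000181   0.0204     6.05

[1] 1.2
```

The stable points far from the indentation report near-zero deformation
while those near it approach the scheduled amplitude; the fitted Gaussian
peak (`peak_mm`) recovers the occluded 10 mm tool-tip displacement to about
a tenth of a millimeter, and the force readout matches the label generated
through the same material model (1.2 N at 10 mm for the demo model) to
within 0.05 N.

`plot_deformation(field, frames[[5]]$img_L)` renders the heatmap overlay
with a mm color scale; `autoplot()` works on point clouds, deformation
fields and material models.

A command-line front end is installed with the package
(`inst/cli/tissuedeform`) exposing `simulate`, `reconstruct`, `track-deform`,
`estimate-force` and `calibrate-material` subcommands over the same
functions.

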