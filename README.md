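# lumbosim

Trephine osteotomy geometry and finite-element biomechanics on parametric
lumbar spine phantoms.

In endoscopic lumbar discectomy the surgeon reaches the L4/5 disc through
a cylindrical trephine corridor, removing lamina and facet-joint bone on
the way.  The entry angle (20–40° for the interlaminar approach, 50–70°
for the transforaminal one), the tool diameter (7/8/9 mm) and the number
of attempts determine how much of the posterior column is sacrificed —
and with it the residual stability of the motion segment.  `lumbosim`
quantifies both sides of that trade-off for researchers studying approach
planning:

* **Osteotomy volume.**  A seeded parametric L3–L5 phantom (superellipse
  vertebral bodies with a 1 mm cortical shell; discs with offset nucleus
  and cartilage endplates; a posterior arch with arched interlaminar
  window; cartilage-capped, curved facet joints) stands in for patient
  CT.  Trephine axes are planned on the intervertebral reference plane
  through the interspace centre C (angle θ from the posterior
  mid-sagittal axis, second attempt offset 5° outward), and the removed
  volume `V(θ, d, attempts) = vol(bone ∩ tool)` is computed by
  constructive-solid-geometry Booleans with a Monte Carlo oracle.
* **Segment biomechanics.**  A structured tetrahedral finite-element
  model (linear C3D4-type elements, truss ligaments, compression-only
  facet contact solved as a linear complementarity problem) evaluates the
  intact segment and five resection variants under a 400 N follower load
  plus 10 Nm moments in six directions, reporting the L4–L5 range of
  motion and maximum von Mises stress in the L4/5 annulus and the
  adjacent endplates.

See `vignettes/methods.Rmd` for the full model description and
`analysis/01...05_*.R` for the numbered study drivers.

## Worked example

```r
library(lumbosim)

model <- generate_phantom()            # default synthetic subject
measure_area_fractions(model)
#> $nucleus_over_disc    0.4
#> $disc_over_vertebra   0.95
#> $ap_offset_ratio      1.62

frame <- build_interspace_frame(model, model$planes$L4_inferior,
                                model$planes$L5_superior)
for (ang in c(20, 30, 40, 50, 60, 70)) {
  tool <- plan_tool(frame, trephine_plan(ang, diameter_mm = 8, attempts = 1))
  iv <- intersect_volume(model, tool$solid, pitch = 0.4)
  cat(sprintf("angle %2d: removed %6.1f mm^3 (L5 sup. facet %5.1f, cartilage %5.1f)\n",
              ang, iv$total, iv$breakdown[["facet_L5_superior"]],
              iv$breakdown[["cartilage"]]))
}
#> angle 20: removed  197.9 mm^3 (L5 sup. facet   0.0, cartilage   0.0)
#> angle 30: removed  491.4 mm^3 (L5 sup. facet  10.7, cartilage   0.0)
#> angle 40: removed  701.8 mm^3 (L5 sup. facet 151.6, cartilage  83.0)
#> angle 50: removed  662.9 mm^3 (L5 sup. facet 401.5, cartilage 127.4)
#> angle 60: removed  542.4 mm^3 (L5 sup. facet 513.5, cartilage  28.9)
#> angle 70: removed  377.8 mm^3 (L5 sup. facet 347.6, cartilage   0.0)
```

The measurements confirm the phantom's construction targets (nucleus 40%
of the disc area, disc complex 95% of the vertebral cross-section,
anterior/posterior offset ratio 1.62).  The volume sweep shows the two
clinical regimes: within the interlaminar fan the removed volume grows
with the angle as the corridor engages more lamina and inferior facet;
the transforaminal fan peaks near 50°, where the corridor rakes along the
curved facet joint (heavy cartilage and superior-process involvement),
and falls off towards 70° as the tool clears the joint laterally.

Cohort-level studies and the finite-element experiment run through the
pipeline functions:

```r
run_volume_study(run_config(n_subjects = 25))   # 900-row factorial + stats
run_biomech_study(run_config())                 # M1-M6 x 6 directions
run_validation()                                # analytic FE + Boolean oracles
```

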