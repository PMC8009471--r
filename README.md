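# nirheat

Photothermal stimulation experiments couple a near-infrared (NIR) laser, a
nanoparticle-coated glass substrate, and cells whose intracellular
temperature is read out with a temperature-sensitive fluorescent dye.
`nirheat` is for researchers who need to turn such measurements into
physical quantities: it models the substrate's temperature increment, 
calibrates the particles' effective absorption fraction against measured
step-end temperature increments, converts fluorescence traces to
temperatures, and quantifies the image-derived inputs (particle coverage,
mitochondrial roundness). A synthetic-data generator with known ground
truth stands in for raw microscopy data, so every stage is testable end to
end.

## The model

The temperature increment ΔT(r, t) = T − T∞ of the thin substrate obeys the
axisymmetric balance

    ρc ∂T/∂t = k (1/r) ∂/∂r (r ∂T/∂r) − (γ/h)(T − T∞) + (ξ/h) I_NIR(r, t)

with conduction (k), surface exchange to water and air (γ = γw + γa),
and a top-hat source I_NIR = P_NIR(t)/(π r_spot²) inside the irradiation
spot. The fraction ξ = ξ_density · ξ_abs of nominal laser power acting as a
heat source factors into the particle occupancy fraction of the irradiated
region (from image binarization) and the particles' effective absorption
fraction, the quantity estimated by least squares against step-end
observations. The PDE is solved by the method of lines (second-order
centered differences, adaptive stiff time integration) and is verified
against an exact modified-Bessel steady-state solution, spatial-order
measurement, and an energy-balance audit.

## Worked example

```r
library(nirheat)

fit <- fit_absorption_fraction(reference_observations())
summary(fit)
#> Calibration of the effective NIR absorption fraction
#>
#>   xi_abs    = 0.2091
#>   xi        = xi_density * xi_abs = 0.17 * 0.2091 = 0.0356
#>   RMSE      = 0.698 K (unweighted least squares)
#>
#>  power_mW t_s observed_K se_K predicted_K residual_K
#>      69.5  60       2.69 0.37       1.592     1.0985
#>     178.0 120       4.70 0.68       4.076     0.6239
#>     286.5 180       6.70 0.94       6.561     0.1392
#>     395.0 240       8.47 0.81       9.045    -0.5754
check_absorption_bound(coef(fit), transmittance = 0.75)$pass
#> [1] TRUE
```

The fit returns the absorption fraction that best scales the model's
center-spot increments onto the four step-end observations. Because the
model relaxes within seconds of each power change, its step-end predictions
are proportional to power, while the measurements flatten at high power —
so the best single-fraction fit undershoots the first step and slightly
overshoots the last, and the 0.698 K RMSE is the model family's floor on
these step-end means (the methods vignette derives why). The calibrated
fraction respects the transmittance-derived physical bound ξ_abs < 0.25.

Thermometry and image quantities:

```r
fluorescence_to_delta_T(0.972)   # a 2.8% decrement reads as +1 degC
#> [1] 1

img <- synth_particle_image(synth_spec(seed = 1, coverage_true = 0.17))
occupancy_fraction(img)          # Otsu binarization recovers the coverage
#> [1] 0.1699982

masks <- synth_ellipse_masks(synth_spec(seed = 1, axis_ratios = c(0.5, 1)))
roundness(region_shapes(masks$mask))
#> [1] 0.4955542 0.9998479
```

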