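# slscpa — short-lag spatial coherence beamforming for photoacoustic imaging

Interventional photoacoustic imaging localizes the tip of an optical fiber
inside tissue: a nanosecond laser pulse delivered through the fiber
generates an acoustic wave that a linear ultrasound array records as one
frame of radio-frequency channel data. At skin-safe pulse energies the
signal can fall below the noise floor of conventional delay-and-sum (DAS)
beamforming. Short-lag spatial coherence (SLSC) imaging instead displays
the spatial coherence of the delayed receive signals — high for a point
source, near zero for electronic noise — and recovers targets DAS loses.
This package is for researchers who want that pipeline, its image-quality
metrics, and a closed-loop probe-servoing simulation in plain R, end to end
on synthetic channel data.

## The method

A frame is delayed onto the image grid with one-way receive delays
(`z = c t / fs`), giving complex aperture signals `s_i(z, x)` per element
`i`. DAS forms `|Σ_i s_i(z,x)|`. SLSC forms, per lag `m` (element
separation),

    C_ij(z,x,m) = Σ_{i=1}^{Ni−m} s_i(z,x) s_{i+m}(z,x)*
    C_ii(z,x,m) = Σ |s_i|²,   C_jj(z,x,m) = Σ |s_{i+m}|²

and compounds them over an axial kernel of `k` samples and the first `M`
lags:

    SLSC(z,x) = Σ_{m=1}^{M}  Re(Σ_k C_ij) / sqrt(Σ_k C_ii · Σ_k C_jj)

Each lag term is an ensemble correlation coefficient in [−1, 1]; negative
compounded values are clipped to zero, then the image is normalized and
log-compressed for display. Image quality is assessed with the generalized
contrast-to-noise ratio (gCNR, one minus the overlap of 256-bin amplitude
histograms inside/outside the target), lateral full width at half maximum,
and the ratio of target-ROI mean to background-ROI standard deviation.
A segmentation (threshold → largest 8-connected component → morphological
regularization → intensity-weighted centroid) drives a proportional
visual-servoing controller, and a laser-safety module computes the skin
maximum permissible exposure and the per-pulse fiber energy limit.

See `vignettes/slsc-photoacoustic-beamforming.Rmd` for the full model,
parameter guidance, and design rationale.

## Worked example

A 128-element, 0.3 mm pitch, 40 MHz array images a point source at 40 mm
depth, 2 mm lateral, with channel SNR −15 dB:

```r
library(slscpa)
geom  <- array_geometry()                       # 128 el, 40 MHz, 1540 m/s
frame <- simulate_channel_data(geom, source_spec(lateral = 2, depth = 40),
                               depth = 50, noise_snr_db = -15, seed = 1)
slsc <- beamform_frame(frame, method = "slsc", M = 25, k = 11)
das  <- beamform_frame(frame, method = "das")

tgt  <- locate_target(slsc$image)               # brightest pixel, in mm
rois <- default_rois(tgt)
gcnr(slsc$image, rois$inside, rois$outside)
image_snr(slsc$image, tgt)$mean
segment_target(slsc$image)$centroid
```

which prints (same seed):

```
target lateral/axial: 1.95 40.0015        # argmax vs true (2, 40) mm
gCNR slsc: 0.389      gCNR das: 0.196     # discrimination probability proxy
SNR  slsc: 57.9 ± 22.5   das: 4.5 ± 0.1   # target mean / background sd
centroid lateral/axial: 1.97 39.98        # segmentation, mm
```

At this noise level the coherence image separates the target from the
background far better than the amplitude image (gCNR roughly doubled, an
order of magnitude in image SNR), while both localize the source to within
one pixel; the energy-limit chain prints

```r
energy_limit(900, 1.0)
#> <pa_energy_limit> 900 nm: MPE 50.24 mJ/cm^2; 1-mm fiber core -> 394.6 uJ/pulse
```

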