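# segwave

Simulation and analysis of segmentation-clock waves in the vertebrate
embryo, for developmental biologists and modellers studying somitogenesis.

During somite formation, the presomitic mesoderm (PSM) sustains traveling
waves of oscillating gene expression: cellular oscillators slow down along
the body axis, and one segment is laid down each time a wave completes a
cycle at the anterior end of the PSM. Because the PSM itself shortens while
this happens, the anterior end moves *into* the wave pattern — a Doppler
effect — while the pattern's wavelength simultaneously shrinks — a dynamic
wavelength effect. The balance of the two sets the pace of segmentation.

`segwave` implements a continuum phase-oscillator model of this process.
The tissue phase $\phi(x,t)$ (unwrapped, radians) obeys

$$\partial_t \phi + v\,\partial_x \phi = \omega + \tfrac{\varepsilon}{2}\,\partial_x^2 \phi,$$

with a frequency profile $\omega = \omega_0 U(x/\bar{x}(t))$ (maximal at
the posterior tip, decaying to $\sigma\omega_0$ at the anterior end, zero
beyond it), a cell-velocity field $v = v_0 (1 - e^{-q x/\bar{x}(t)})$, a
diffusive phase coupling $\varepsilon$, and a shortening tissue
$\bar{x}(t) = x_0 + x_1\tanh\eta(t-\bar{t})$. From a solved field the
package derives the observables used in quantitative studies — the wave
count $K$, segment count $N$, segment length
$S \simeq 2\pi/|\partial_x\phi(\bar{x},t)|$, and the decomposition of the
anterior segmentation frequency
$\Omega_A = \Omega_P + \Omega_D + \Omega_W$ into posterior, Doppler and
dynamic-wavelength contributions. It also provides time-periodic solutions
with their weak-coupling approximations, exact classical-wave analogues of
both effects, parameter fitting from tabular data (PSM-length series,
boundary tracks, phase kymographs), and seeded synthetic-data generators
for all three data kinds. The default parameters are a zebrafish
calibration; see `zebrafish_parameters()` and the methods vignette
(`vignettes/segmentation-waves.Rmd`).

## A worked example

```r
library(segwave)

mp <- zebrafish_parameters()
sc <- simulation_config(t_end = 520, dx = 1, L = 900, output_stride = 2L)
pf <- simulate_phase_field(mp, sc)
pf
#> Phase field: 3394 frames x 901 nodes
#>   t in [-256, 520] min (frame spacing 0.228706 min)
#>   x in [0, 900] um (dx = 1 um); PSM length 614.82 -> 228.839 um

recs <- extract_segments(pf)
recs$index <- recs$index + staging_offset(recs)   # 7th segment at t = 0
head(subset(recs, formation_time >= 0), 8)
#>  index formation_time length anterior_position
#>      7          23.45  61.67             557.4
#>      8          67.18  62.53             530.5
#>      9         106.87  64.03             499.4
#>     10         144.03  65.48             465.4
#>     11         179.88  65.75             429.4
#>     12         215.36  66.87             393.1
#>     13         251.30  62.94             357.8
#>     14         288.26  61.98             325.3

dec <- decompose_anterior_frequency(pf)
round(colMeans(dec[dec$t >= 0 & dec$t <= 450, -1]), 4)
#> Omega_A Omega_P Omega_D Omega_W
#>  0.1600  0.1481  0.0779 -0.0660
```

Reading the output: the simulation starts from a uniform phase at
`t0 = -256` min and covers the 500-minute observation window. Segments
form roughly every 35–45 minutes; their length is non-monotonic, peaking
at segment 12 (66.9 um) before shrinking as the PSM shortens. The
frequency decomposition shows the hallmark of the shortening tissue: the
Doppler contribution (+0.078 rad/min) outweighs the dynamic-wavelength
contribution (−0.066 rad/min), so the anterior frequency (0.160 rad/min)
exceeds the posterior clock frequency (0.148 rad/min) — segments form
faster than any single oscillator in the tissue cycles. The wave count
drops from 2.6 to 1.7 over the same window. `plot(pf)` draws the
kymograph of $\sin\phi$ with the anterior end overlaid.

A thin command-line front end over the same functions is installed at
`inst/cli/segwave.R` (subcommands `simulate`, `observe`, `periodic`,
`fit`, `fixture`, `demo`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/segwave.R", package = "segwave"))')" \
  simulate --t-end 520 --out run/
```

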