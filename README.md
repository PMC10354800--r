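# nicospec

Freebase nicotine fraction of e-cigarette liquids from a single non-aqueous
pH measurement.

## The problem

Nicotine in an e-liquid partitions between its neutral **freebase** (fb)
form — the one associated with inhalation harshness — and the
**monoprotonated** (mp) "salt" form, according to the pH of the matrix.
That matrix is a propylene glycol / vegetable glycerin (PG/VG) mixture, not
water, which defeats the usual aqueous Henderson–Hasselbalch treatment in
two ways: an aqueous-calibrated electrode reads an apparent pH offset from
the real one by a solvent-specific constant δ, and nicotine's pKa shifts
with the solvent's dielectric constant D. Both effects are linear in D over
the PG/VG–water range, so a corrected speciation formula needs only two
measurable inputs, pH<sup>app</sup> and D:

```
pKa(D) = a·D + b          (nicotine:  a = −0.015, b = 9.19)
δ(D)   = f·D + g          (f = 0.04, g = −3.22)

fb = 1 / (1 + 10^[ pKa(D) − (pH_app − δ(D)) ]),   mp = 1 − fb
```

D itself follows from the PG/VG volume composition via mole fractions
(densities 1.036 / 1.261 g/mL, molar masses 76.09 / 92.09 g/mol) and the
mole-fraction-linear mixing rule between the endpoints 27.5 (PG) and 42.5
(VG). The package implements this pipeline, the potentiometric-titration
analysis that produced the calibration (first-derivative equivalence point,
half-equivalence pKa, δ from strong-acid/strong-base titrations), Davies
activity utilities, a charge-balance titration simulator with known ground
truth, and a validation report against the liquid–liquid-extraction (LLE)
reference method for 22 commercial and lab-made liquids.

It is intended for tobacco-regulatory and analytical-chemistry users who
have a non-aqueous pH meter and either a dielectric-constant meter or the
liquid's PG/VG composition.

## Worked example

A commercial pod (NJOY Ace-Classic Tobacco, 28 mg/mL nicotine) with a
52.33/47.67 PG/VG composition reads an apparent pH of 6.06:

```r
library(nicospec)

solvent_mixture(52.33, 47.67)
#> PG/VG 52.33/47.67 %v/v  (x_PG = 0.5219)  D = 34.67

fraction_fb_from_measurements(6.06, 34.67, nicotine_conc = 28,
                              label = "NJOY Ace-Classic Tobacco")
#>                      label ph_app     D   delta   ph_s     pka fraction_fb
#> 1 NJOY Ace-Classic Tobacco   6.06 34.67 -1.8332 7.8932 8.66995   0.1432527
#>   fraction_mp nicotine_conc  conc_fb  conc_mp
#> 1   0.8567473            28 4.011075 23.98892
```

Reading the row: at D = 34.67 the solvent offset is δ = −1.83, so the real
pH is 7.89, almost two units above the electrode reading; nicotine's pKa in
this mixture is 8.67; hence 14.3% of the nicotine is freebase (fb = 0.143
after rounding) and 24.0 of the 28 mg/mL is in the protonated salt form.
The LLE reference method gives fb = 0.150 for this liquid — a 0.8% relative
difference on the mp quantities.

Re-running the whole 22-liquid validation:

```r
rep <- reproduce_table2()
attr(rep, "n_flags")
#> [1] 0
```

A thin CLI over the same functions is installed as `exec/nicospec`
(subcommands `fb`, `calibrate`, `titrate`, `simulate`, `validate`).

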