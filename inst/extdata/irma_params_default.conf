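# Default calibration of the IRMA hybrid DDE model shipped with cyberloop.
# These are the package's own defaults, chosen to reproduce the network's
# characteristic qualitative behaviour (galactose switch-on, several-fold
# Cbf1 ON/OFF separation, settling over hundreds of minutes, ~100 min
# transcriptional delay at the HO promoter). Concentrations in model units,
# times in minutes. Species order: cbf1, gal4, swi5, ash1, gal80.

# basal transcription rates (units/min)
basal_cbf1  = 0.003
basal_gal4  = 0.001
basal_swi5  = 0.002
basal_ash1  = 0.001
basal_gal80 = 0.001

# maximal regulated production rates (units/min)
vmax_cbf1  = 0.06
vmax_gal4  = 0.04
vmax_swi5  = 0.09
vmax_ash1  = 0.03
vmax_gal80 = 0.03

# Hill thresholds (model units)
# k1: Swi5 -> CBF1 activation (HO promoter, delayed)
# k2: Ash1 -| CBF1 repression (HO promoter, delayed)
# k3: Cbf1 -> GAL4 activation
# k4: free Gal4 -> SWI5 activation (GAL10 promoter, galactose-gated)
# k5: Swi5 -> ASH1 activation
# k6: Swi5 -> GAL80 activation
k1 = 0.8
k2 = 1.2
k3 = 0.25
k4 = 0.45
k5 = 0.6
k6 = 1.0

# Hill coefficients
h1 = 2
h2 = 2
h3 = 2
h4 = 2
h5 = 2
h6 = 2

# degradation + dilution rates (1/min)
deg_cbf1  = 0.02
deg_gal4  = 0.02
deg_swi5  = 0.03
deg_ash1  = 0.06
deg_gal80 = 0.02

# Gal80p-Gal4p protein-protein inhibition constant (model units)
gamma = 0.6

# transcriptional delay on HO-driven Cbf1 production (min)
tau = 100
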