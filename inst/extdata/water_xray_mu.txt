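# Photon mass attenuation coefficient (mu/rho, with coherent) in liquid water
# columns: energy_keV  mu_over_rho_cm2_per_g
# 1-10 keV: standard NIST-XCOM-style evaluated values
# 0.5-1 keV: approximate power-law extension (below the oxygen K edge region)
# valid domain: 0.5 to 10 keV; density 1.0 g/cm3
5.0000e-01 3.2000e+04
6.0000e-01 1.8900e+04
8.0000e-01 8.0800e+03
1.0000e+00 4.0780e+03
1.5000e+00 1.3760e+03
2.0000e+00 6.1730e+02
3.0000e+00 1.9290e+02
4.0000e+00 8.2780e+01
5.0000e+00 4.2580e+01
6.0000e+00 2.4630e+01
8.0000e+00 1.0370e+01
1.0000e+01 5.3290e+00
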