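# Electron total mass stopping power in liquid water
# columns: energy_MeV  stopping_power_MeV_cm2_per_g
# rows >= 10 keV: Berger-Seltzer collision formula (I = 75 eV, Z/A = 0.55509)
#   plus approximate radiative correction (~Z(E+mc2)/800); agrees with ESTAR
# rows <  10 keV: package-owned track-structure-style values for liquid water,
#   adjusted to reproduce published low-energy LET and CSDA-range anchors
#   (7 keV/um at 2 keV, 26 keV/um at 150 eV, 120 nm CSDA at 2 keV)
# valid domain: 7.4e-6 to 1.0 MeV; density 1.0 g/cm3
7.400000e-06 2.000000e+01
1.000000e-05 3.200000e+01
2.000000e-05 6.200000e+01
3.000000e-05 9.200000e+01
5.000000e-05 1.450000e+02
8.000000e-05 2.050000e+02
1.000000e-04 2.350000e+02
1.500000e-04 2.620000e+02
2.000000e-04 2.850000e+02
3.000000e-04 2.900000e+02
5.000000e-04 2.820000e+02
7.000000e-04 2.580000e+02
1.000000e-03 2.160000e+02
1.400000e-03 1.580000e+02
1.700000e-03 1.120000e+02
2.000000e-03 7.800000e+01
2.500000e-03 6.600000e+01
3.000000e-03 5.800000e+01
4.000000e-03 4.650000e+01
5.000000e-03 3.900000e+01
6.000000e-03 3.380000e+01
8.000000e-03 2.690000e+01
1.000000e-02 2.267031e+01
1.154782e-02 2.027511e+01
1.333521e-02 1.813053e+01
1.539927e-02 1.621279e+01
1.778279e-02 1.450001e+01
2.053525e-02 1.297212e+01
2.371374e-02 1.161072e+01
2.738420e-02 1.039908e+01
3.162278e-02 9.321946e+00
3.651741e-02 8.365496e+00
4.216965e-02 7.517212e+00
4.869675e-02 6.765786e+00
5.623413e-02 6.101023e+00
6.493816e-02 5.513749e+00
7.498942e-02 4.995725e+00
8.659643e-02 4.539559e+00
1.000000e-01 4.138637e+00
1.154782e-01 3.787045e+00
1.333521e-01 3.479504e+00
1.539927e-01 3.211308e+00
1.778279e-01 2.978267e+00
2.053525e-01 2.776654e+00
2.371374e-01 2.603153e+00
2.738420e-01 2.454815e+00
3.162278e-01 2.329018e+00
3.651741e-01 2.223422e+00
4.216965e-01 2.135939e+00
4.869675e-01 2.064700e+00
5.623413e-01 2.008024e+00
6.493816e-01 1.964396e+00
7.498942e-01 1.932445e+00
8.659643e-01 1.910931e+00
1.000000e+00 1.898726e+00
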