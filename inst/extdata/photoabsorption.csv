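# Total photoabsorption cross sections (nm^2/atom) for 6-10 keV photons.
# C, N, O, S: sigma = 2 * r_e * lambda * f2 with f2 from the Cromer-Liberman
#   anomalous-dispersion tabulation (Cromer & Liberman, J. Chem. Phys. 53, 1891
#   (1970); evaluated via the gemmi implementation), r_e = 2.8179403e-6 nm.
# H: below the Cromer-Liberman range; hydrogenic estimate anchored at
#   sigma(8 keV) = 8.0e-13 nm^2 (Henke-scale f2) with an E^-3.2 energy law.
# core_fraction: share of the total assigned to the K shell (core), estimated
#   from absorption edge-jump ratios; H by convention has no core shell.
element,energy_kev,sigma_total_nm2,core_fraction
H,6,2.010e-12,0.00
H,7,1.227e-12,0.00
H,8,8.000e-13,0.00
H,9,5.491e-13,0.00
H,10,3.918e-13,0.00
C,6,1.9886e-08,0.95
C,7,1.2231e-08,0.95
C,8,8.0104e-09,0.95
C,9,5.5037e-09,0.95
C,10,3.9192e-09,0.95
N,6,3.9078e-08,0.95
N,7,2.4215e-08,0.95
N,8,1.5946e-08,0.95
N,9,1.1005e-08,0.95
N,10,7.8687e-09,0.95
O,6,6.9031e-08,0.94
O,7,4.3054e-08,0.94
O,8,2.8511e-08,0.94
O,9,1.9771e-08,0.94
O,10,1.4223e-08,0.94
S,6,1.1072e-06,0.87
S,7,7.1834e-07,0.87
S,8,4.9165e-07,0.87
S,9,3.5065e-07,0.87
S,10,2.5836e-07,0.87
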