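# Brain tissue constitutive parameters (calibrated for impact strain rates,
# ~1/s mean). Units as stated per key; loaders convert to SI (Pa).
version: 1
white_matter:
  rho_o: 1140        # kg/m^3
  K_o_GPa: 2.19
  Lambda_o: 6.15
  mu_m_kPa: 550
  j_m: 1.1
  k1_kPa: 2.14
  k2: 0              # dimensionless in the exponential of the fiber term
gray_matter:
  rho_o: 1140
  K_o_GPa: 2.19
  Lambda_o: 6.15
  mu_m_kPa: 450
  j_m: 1.4
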