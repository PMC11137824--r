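# Electron-water pseudopotential, screened-Coulomb + Gaussian form.
#
# Per site:  V(r) = -kc * q * erf(A r) / r  +  sum_i B_i exp(-C_i r^2)
# with kc the Coulomb constant (14.3996 eV A), q the site partial charge
# in units of e (the electron carries charge -e), A in 1/A, B in eV and
# C in 1/A^2.  Beyond the screening length 1/A the Coulomb term tends to
# the bare charge-charge interaction, matching the water model's partial
# charges at long range; the Gaussian terms supply the short-range
# repulsion that keeps the electron out of the molecular cores.
#
# SYNTHETIC PARAMETER SET: this is a representative parameterization of
# the screened-Coulomb functional form, chosen to give qualitatively
# correct cavity binding of the excess electron (bound ground state,
# s->p type low-lying transitions).  It is not a transcription of any
# published electron-water parameter table.
name: tb-style-synthetic
elements:
  O:
    A: 1.20          # 1/A
    gauss:
      - {B: 15.0, C: 1.20}   # core exclusion at the oxygen
  H:
    A: 2.50          # 1/A
    gauss:
      - {B: 0.50, C: 2.00}   # mild repulsion at the hydrogens
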