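# Flexible simple point-charge water parameter set.
# Harmonic stretch/bend constants follow the published flexible-SPC
# (SPC/Fw-style) parameterization; the stretch constant gives an OH
# stretch fundamental near 3600-3700 cm^-1.  Energies in eV, lengths in
# A, angles in degrees.  Intramolecular terms are E = k/2 (x - x0)^2.
name: flexible-SPC
r0: 1.012            # A, equilibrium OH bond
theta0_deg: 113.24   # degrees, equilibrium HOH angle
kr: 45.93            # eV/A^2, OH stretch force constant
ktheta: 3.291        # eV/rad^2, HOH bend force constant
epsilon: 0.006739    # eV, O-O Lennard-Jones well depth
sigma: 3.165492      # A, O-O Lennard-Jones diameter
qO: -0.82            # e
qH: 0.41             # e
cutoff: 9.0          # A, spherical cutoff r_c (desk-scale default)
taper: 1.0           # A, taper width: switch is smooth on [r_c - 1, r_c]
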