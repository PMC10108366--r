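# Fitted photophysical parameter values for SCy7 in PBS (12 mM, pH 7.2).
# Three parameter sets: a global FCS fit at 638 nm excitation and global TRAST
# fits at 638 nm and 785 nm excitation. Cross sections are keyed by excitation
# wavelength (nm); Q values by emission band label (B / R / FR).
# sigma_N was fixed from the absorption spectrum and the manufacturer
# extinction coefficient (240,600 L mol^-1 cm^-1): 1.56e-16 cm^2 at 638 nm,
# 2.48e-16 cm^2 at 785 nm. tau_f fixed to 0.52 ns from TCSPC.

[set: fcs638]
k_iso1 = 12.5e6           # s^-1
sigma_N@638 = 1.56e-16    # cm^2
sigma_biso1@638 = 1.1e-18 # cm^2 (0.011e-16)
sigma_iso2@638 = 3.0e-17  # cm^2 (0.3e-16)
sigma_biso2@638 = 1.3e-17 # cm^2 (0.13e-16)
k_biso1_th = 0            # s^-1 (fixed to 0 in the FCS fit)
k_biso2_th = 0            # s^-1 (fixed to 0 in the FCS fit)
tau_f = 0.52e-9           # s
Q@B = 0                   # fixed to 0 (B-filter emission is from N only)

[set: trast638]
k_iso1 = 14e6             # s^-1
sigma_N@638 = 1.56e-16    # cm^2
sigma_biso1@638 = 1.2e-18 # cm^2 (0.012e-16)
sigma_iso2@638 = 2.0e-17  # cm^2 (0.2e-16)
sigma_biso2@638 = 2.0e-17 # cm^2 (0.2e-16)
k_biso1_th = 3.4e4        # s^-1 (0.034 us^-1)
k_biso2_th = 1.1e4        # s^-1 (0.011 us^-1)
tau_f = 0.52e-9           # s
tau_f2 = 0.3e-9           # s
Q@B = 0
Q@R = 0.56

[set: trast785]
k_iso1 = 14e6             # s^-1 (fixed from the 638 nm fit)
sigma_N@638 = 1.56e-16    # cm^2
sigma_N@785 = 2.48e-16    # cm^2
sigma_biso1@638 = 1.2e-18 # cm^2
sigma_biso1@785 = 1.68e-17 # cm^2 (F = 14 times the 638 nm value)
sigma_iso2@638 = 2.0e-17  # cm^2
sigma_iso2@785 = 2.8e-16  # cm^2 (F = 14 times the 638 nm value)
sigma_biso2@638 = 2.0e-17 # cm^2
sigma_biso2@785 = 2.9e-16 # cm^2 (14.5 times the 638 nm value)
k_biso1_th = 3.4e4        # s^-1 (fixed from the 638 nm fit)
k_biso2_th = 1.1e4        # s^-1 (fixed from the 638 nm fit)
tau_f = 0.52e-9           # s
tau_f2 = 0.3e-9           # s
Q@B = 0
Q@R = 4.6
Q@FR = 5.6
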