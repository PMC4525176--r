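# Shared study objects: the two reference molecules and the experimental
# rotating-field protocol (6e5 V/m, 0.9 MHz, 293 K, benzene).
mol1 <- reference_rotor("molecule_I")
mol2 <- reference_rotor("molecule_II")
ref_field <- reference_field()

# hand-converted dimensionless couplings at 6e5 V/m, 293 K
# (mu[D] * 3.33564e-30 * 6e5 / (1.380649e-23 * 293))
X_MOL1 <- 2.62214e-3
X_MOL2 <- 5.39270e-3
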