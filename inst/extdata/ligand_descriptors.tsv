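# Quantum-mechanical descriptors of myo-inositol phosphates (DFT
# B3LYP/6-31+G(d,p)); packaged reference values, consumed read-only for
# report context and never recomputed here.
ligand	electronic_spatial_extent_A2	dipole_moment_debye	energy_HF_au	energy_MP2_au	denergy_MP2_kcal
Ins(1,3,4)P3	10026	17.2	-2369.20	-2371.76	6.4
Ins(1,4,5)P3	9868	11.7	-2369.21	-2371.77	0.0
Ins(1,3,4,5)P4	13820	10.6	-2932.45	-2951.77	NA
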