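# Default classifier thresholds.
# Calibrated once as midpoints between the synthetic archetype group means
# (100 cases/group, effect 1.0, calibration seed 42); reproduce with
# analysis/03_calibrate_thresholds.R.
# tau_hydrophobic_peak: midpoint of Group 1 vs Group 3 mean beta1/beta2
#   smoothed-hydropathy maxima (Kyte-Doolittle units).
# tau_charge: midpoint of Group 2 vs Group 4 mean charge-concentration
#   maxima (ECI units).
# tau_hydrophilic: midpoint of Group 2 vs Group 4 mean loop hydrophilicity
#   (negated mean smoothed hydropathy).
tau_hydrophobic_peak: 0.9851
tau_charge: 1.0421
tau_hydrophilic: 1.7072
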