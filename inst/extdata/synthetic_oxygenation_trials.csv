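# SYNTHETIC, ILLUSTRATIVE study table for the evidence-based prior.
# These arm counts are invented placeholders with plausible magnitudes for
# three previous lower-vs-higher oxygenation RCTs; they are NOT transcribed
# from any publication. Replace with real counts before substantive use.
# Columns: study, events/size in the lower-target (intervention) arm,
# events/size in the higher-target (control) arm.
study,e_int,n_int,e_ctl,n_ctl
synthetic_trial_small,25,216,44,218
synthetic_trial_ards,44,99,31,102
synthetic_trial_large,168,484,157,481
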