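# Synthetic Hildebrand inputs for the three cocoa-butter TAGs.
# T_m_C: simulated pure-TAG melting points (same values as the 0/100 and
#   100/0 rows of simulated_melting_points.csv).
# dH_f_J_mol: SYNTHETIC placeholder enthalpies of fusion, plausible in
#   magnitude for beta-2 monounsaturated TAGs but NOT literature values;
#   substitute measured enthalpies for real predictions.
species,T_m_C,dH_f_J_mol
POP,33.5,92000
POST,34.4,98000
STOST,38.9,104000
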