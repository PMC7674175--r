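task,phase,mode,reference_trials
a_minus,1,intact,2
a_minus,1,lesioned,2
a_plus,1,intact,26
a_plus,1,lesioned,18
blocking,1,intact,26
blocking,1,lesioned,18
blocking,2,intact,27
blocking,2,lesioned,22
blocking,3,intact,17
blocking,3,lesioned,6
stimulus_discrimination,1,intact,28
stimulus_discrimination,1,lesioned,19
discrimination_reversal,1,intact,28
discrimination_reversal,1,lesioned,19
discrimination_reversal,2,intact,26
discrimination_reversal,2,lesioned,37
easy_hard_transfer,1,intact,30
easy_hard_transfer,1,lesioned,24
easy_hard_transfer,2,intact,37
easy_hard_transfer,2,lesioned,26
context_shift,1,intact,29
context_shift,1,lesioned,17
context_shift,2,intact,1
context_shift,2,lesioned,1
context_sensitivity_latent_inhibition,1,intact,25
context_sensitivity_latent_inhibition,2,intact,1
generic_feedforward,1,lesioned,25
generic_feedforward,2,lesioned,20
sensory_preconditioning,1,intact,25
sensory_preconditioning,2,intact,34
sensory_preconditioning,3,intact,50
latent_inhibition,1,intact,25
latent_inhibition,1,lesioned,25
latent_inhibition,2,intact,35
latent_inhibition,2,lesioned,23
overshadowing,1,intact,10
overshadowing,1,lesioned,10
overshadowing,2,intact,24
overshadowing,2,lesioned,19
compound_preconditioning,1,intact,10
compound_preconditioning,2,intact,30
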