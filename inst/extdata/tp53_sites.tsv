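# Case study: cellular tumor antigen p53 (Homo sapiens).
# set = experimental: experimentally confirmed ubiquitylation sites;
# set = predicted: sites reported by a published sequence-based predictor.
set	position
experimental	101
experimental	120
experimental	132
experimental	164
experimental	291
experimental	292
experimental	305
experimental	320
experimental	321
experimental	357
experimental	370
predicted	101
predicted	120
predicted	291
predicted	292
predicted	305
predicted	319
predicted	320
predicted	321
predicted	351
predicted	357
predicted	382
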