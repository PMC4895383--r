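# Case study: E3 ubiquitin-protein ligase DMA2 (Saccharomyces cerevisiae).
# set = experimental: experimentally confirmed ubiquitylation sites;
# set = predicted: sites reported by a published sequence-based predictor.
set	position
experimental	211
experimental	256
experimental	258
experimental	288
experimental	310
experimental	333
experimental	343
experimental	346
experimental	366
experimental	406
experimental	412
experimental	423
predicted	211
predicted	258
predicted	288
predicted	310
predicted	343
predicted	346
predicted	366
predicted	412
predicted	423
predicted	516
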