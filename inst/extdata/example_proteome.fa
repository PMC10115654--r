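>ZFC3H1_fragment disordered-region fragment carrying (PLP)x4
LPPPPQVSSLPPLSQPYVEGLCVSLEPLPPLPPLPPLPPEDPEQPPKPPFADEEEEEEML
LREELLKSLANKRAFKPEETSSNSDPPSPPVLNNSHPVPRSNL
>synthetic_tandem synthetic sequence with LRP/PEW/PLP runs
MAGTLRPPEWPLPIYPKDEAAPKWIRPLRTGGS
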