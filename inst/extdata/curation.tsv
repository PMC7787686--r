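variant_key	acmg_class	onset_override
5:112175211:T:A	4	adult
11:108196003:G:C	4	adult
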