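# Signature motif(s) for 3-phosphate binding near the beta1/beta2 loop.
# Pattern syntax: residue letters, "." or x = any residue, [..] = character
# set, (m,n)/{m,n} = bounded repeat, optional "-" separators (PROSITE-like).
# Unbounded repeats are rejected. The default pattern follows the published
# basic-residue PtdIns(3,4,5)P3-binding signature spanning beta1/beta1-beta2;
# it is a configurable default, not an assertion of the original definition.
3p_signature	K-x-[SG]-x(6,11)-[KR]-x-R
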