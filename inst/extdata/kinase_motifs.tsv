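# Kinase consensus motifs over positions -6..+6 (center = phosphosite).
# One motif per line: KINASE<TAB>pattern. Bracketed sets, '.' wildcard.
# Literature consensus patterns; proline-directed kinases (p38 MAPK, JNK,
# CDK) share the S/T-P core, CDK adds the +3 basic residue.
CK2	......[ST]..[DE]...
CK1	...[DE]..[ST]......
PKA	...RR.[ST]......
GSK3	......[ST]...[ST]..
p38 MAPK	......[ST]P.....
JNK	......[ST]P.....
CDK	......[ST]P.[KR]...
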