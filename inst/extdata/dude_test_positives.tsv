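target_id	positives
aa2ar	482
abl1	182
aces	453
ada	93
casp3	199
cp3a4	170
egfr	542
fa10	537
fgfr1	139
fnta	592
grik1	101
hdac8	170
kit	166
kith	57
kpcb	135
pa2ga	99
parp1	508
pgh1	195
ptn1	130
pygm	77
pyrd	111
tgfr1	133
wee1	102
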