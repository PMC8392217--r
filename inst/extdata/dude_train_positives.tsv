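target_id	positives
adrb1	247
adrb2	231
akt2	117
ampc	48
andr	269
aofb	122
bace1	283
braf	152
cah2	492
cdk2	474
cp2c9	120
csf1r	166
cxcr4	40
def	102
dhi1	330
drd3	480
dyr	231
esr1	383
esr2	367
fa7	114
fabp4	47
fak1	100
fkb1a	111
fpps	85
gcr	258
glcm	54
hdac2	185
hivint	100
hivpr	536
hivrt	338
hmdh	170
hs90a	88
hxk4	92
igf1r	148
inha	43
ital	138
jak2	107
kif11	116
lck	420
mapk2	101
mcr	94
mk01	79
mk10	104
mk14	578
mmp13	572
nos1	100
nram	98
pde5a	398
pgh2	435
plk1	107
pnph	103
ppara	373
ppard	240
pparg	484
prgr	293
pur2	50
reni	104
rock1	100
rxra	131
sahh	63
src	524
thb	103
try1	449
tryb1	148
tysy	109
urok	162
vgfr2	409
xiap	100
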