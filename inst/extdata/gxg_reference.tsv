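# gxg_reference ensemble_size=30 seed=20220424 radii=C=1.87,N=1.65,O=1.4,S=1.85;probe=1.4
aa	area
A	63.9148460605872
C	97.285970753348
D	107.602197664355
E	135.536445502532
F	178.867322682293
G	82.8127444608135
H	153.866465818605
I	142.26990298018
K	159.482884911507
L	138.168789783067
M	152.035072068633
N	116.401587022255
P	104.137481865268
Q	141.914925568705
R	186.74105009876
S	74.7432061121044
T	103.246149110325
V	118.190443127732
W	220.443308343786
Y	187.558252000853
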