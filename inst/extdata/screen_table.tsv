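gene	regulation	category
sma-1	upregulated	Shortened
mod-5	upregulated	Shortened
mfb-1	upregulated	Shortened
mrp-2	upregulated	Unchanged
cft-1	upregulated	Unchanged
M116.2	upregulated	Unchanged
cht-1	upregulated	Unchanged
Y71G12B.31	upregulated	Extended<5%
ZC373.4	upregulated	Extended<5%
fkh-7	upregulated	Extended>=5%
csp-2	upregulated	Extended>=5%
lgg-1	upregulated	Extended>=5%
Y50C1A.1	upregulated	Extended>=5%
calu-1	downregulated	Shortened
spds-1	downregulated	Shortened
ssq-1	downregulated	Shortened
act-4	downregulated	Shortened
fat-7	downregulated	Shortened
act-1	downregulated	Shortened
cpn-2	downregulated	Unchanged
tba-9	downregulated	Unchanged
ifa-1	downregulated	Unchanged
ost-1	downregulated	Unchanged
ssq-4	downregulated	Unchanged
ssq-3	downregulated	Unchanged
ifc-1	downregulated	Unchanged
plk-3	downregulated	Extended<5%
tba-6	downregulated	Extended<5%
ifb-2	downregulated	Extended<5%
F13A7.1	downregulated	Extended<5%
ifb-1	downregulated	Extended<5%
ifc-2	downregulated	Extended<5%
cyb-2.1	downregulated	Extended<5%
bcat-1	downregulated	Extended>=5%
T25B9.1	downregulated	Extended>=5%
ndk-1	downregulated	Extended>=5%
ifd-1	downregulated	Extended>=5%
tba-4	downregulated	Extended>=5%
ifa-3	downregulated	Extended>=5%
try-1	downregulated	Extended>=5%
ifp-1	downregulated	Extended>=5%
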