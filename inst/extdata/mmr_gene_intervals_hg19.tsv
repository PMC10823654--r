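gene	chrom	start	end
MLH1	chr3	37034823	37107380
MSH2	chr2	47630108	47789450
MSH6	chr2	47922669	48037240
PMS2	chr7	6012870	6048756
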