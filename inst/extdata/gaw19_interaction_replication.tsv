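gene	probe	snp1	chr1	snp2	chr2	p
ATP13A1	GI_9966896-S	rs4284750	19	rs873870	19	0.000101
CSTB	GI_20357564-S	rs9979356	21	rs3761385	21	0.000747
CTSC	GI_22538439-I	rs7930237	11	rs556895	11	0.020446
CTSC	GI_22538438-I	rs7930237	11	rs556895	11	0.636009
FN3KRP	GI_20149679-S	rs898095	17	rs9892064	17	0.015972
GAA	GI_11496988-S	rs11150847	17	rs12602462	17	0.240101
LAX1	GI_8923315-S	rs1891432	1	rs10900520	1	0.205055
MBNL1	GI_41281590-S	rs16864367	3	rs13079208	3	0.01683
MBNL1	GI_41281590-S	rs7710738	5	rs13069559	3	0.938258
MBNL1	GI_41281590-S	rs2186711	7	rs13069559	3	0.178989
MBNL1	GI_41281590-S	rs11981513	7	rs13069559	3	0.307821
PRMT2	GI_4504494-S	rs2839372	21	rs11701058	21	0.4209
TRA2A	GI_33620726-S	rs7776572	7	rs11770192	7	0.51894
VASP	GI_4507868-S	rs1264226	19	rs2276470	19	0.645204
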