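chrom_id	chrom_len	n_indels	n_indel_ssrs
Chr1	212136754	404254	155570
Chr2	200729444	561289	268909
Chr3	187626166	366363	111501
Chr4	159385462	629928	134704
Chr5	175351756	357483	120041
Chr6	151421878	546905	139596
Chr7	112675773	251974	99058
Chr8	179232514	397430	124390
Chr9	156137564	378460	121793
Chr10	154668131	386074	137204
Chr11	133294484	373230	133426
Chr12	102222464	246607	92893
Chr13	104727164	257022	84127
Chr14	117533969	245723	82422
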