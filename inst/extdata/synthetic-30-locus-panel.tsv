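# SYNTHETIC variant panel: 30 loci with GWAS-typical allele frequencies and
# modest per-allele odds ratios, generated by random_panel(30, seed = 2010).
# It is a stand-in for a real susceptibility panel; it does not transcribe
# any published variant list.
id	raf	or
locus01	0.3159	1.5784
locus02	0.5225	1.4333
locus03	0.4981	1.0561
locus04	0.2839	1.0695
locus05	0.8084	1.0769
locus06	0.9068	1.2922
locus07	0.5763	1.448
locus08	0.0865	1.4263
locus09	0.4282	1.5951
locus10	0.0755	1.1508
locus11	0.8835	1.3776
locus12	0.8809	1.328
locus13	0.3152	1.4706
locus14	0.5615	1.5415
locus15	0.1078	1.1306
locus16	0.4296	1.0968
locus17	0.7187	1.2312
locus18	0.2679	1.5455
locus19	0.7072	1.3439
locus20	0.9428	1.3695
locus21	0.7943	1.3299
locus22	0.9478	1.162
locus23	0.8734	1.5451
locus24	0.4718	1.1745
locus25	0.4913	1.1414
locus26	0.2659	1.0678
locus27	0.2812	1.5836
locus28	0.9019	1.3752
locus29	0.5971	1.472
locus30	0.1854	1.3722
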