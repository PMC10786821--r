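# 50-molecule quinoline panel (sa_reference_panel()) with reference Ertl SA scores
# computed with the published reference implementation (frozen oracle values).
smiles	sa_ref
COc1cc2nc(ccc2cc1OC)C(=O)N	1.913787
CC[C@@H](c1cc(Cl)c2c(c1)nccc2N)C	2.852750
COc1cc2nccc(c2cc1N)O	2.303453
CNc1cc(C)c2c(c1)nc(cc2)F	2.302466
CC[C@@H](c1cc(F)c2c(c1)nc(cc2)OC)C	2.707437
CNc1c(ccc2c1ncc(c2)O)C(=O)N	2.548747
CC[C@@H](c1cccc2c1nc(NC)c(c2)SC)C	3.116934
CC[C@@H](c1nc2ccccc2c(c1[C@H](CC)C)N)C	3.169559
CC[C@@H](c1cc(O)c2c(n1)cccc2SC)C	3.077927
CC[C@@H](c1ccc2c(c1)ncc(c2Cl)F)C	2.726231
CC[C@@H](c1nc2ccc(cc2cc1C(=O)N)Cl)C	2.769752
CC[C@@H](c1cc2ncc(cc2cc1C(=O)N)O)C	2.986130
CC[C@@H](c1c(OC)c(C)nc2c1cccc2)C	2.653834
CNc1cc2cccc(c2nc1O)N	2.688582
COc1cc(F)nc2c1cc(C)cc2	2.046522
CC[C@@H](c1ccc2c(n1)cc(c(c2)NC)N)C	2.973180
Nc1cnc2c(c1)cc(c(c2)C(=O)N)F	2.327174
COc1cccc2c1nc(O)c(c2)O	2.362111
CNc1cc(F)cc2c1nccc2N	2.397813
CSc1cc(C)c(c2c1cccn2)C	2.267840
COc1ccc2c(c1)nc(cc2C(=O)N)N	2.066734
NC(=O)c1ccc2c(c1C)c(Cl)ccn2	2.237917
Nc1cc(N)c(c2c1cccn2)C(=O)N	2.442209
CSc1cc2ncccc2c(c1C)O	2.546372
Oc1cnc2c(c1C)c(Cl)ccc2	2.358244
CC[C@@H](c1ccc2c(c1NC)nccc2C)C	2.895559
Oc1ccc2c(n1)c(N)c(cc2)O	2.658521
COc1ccc2c(c1F)c(ccn2)C(=O)N	2.207780
CNc1cc(O)nc2c1ccc(c2)C	2.358408
Clc1cnc2c(c1O)c(N)ccc2	2.456001
Clc1cc(C(=O)N)c2c(n1)c(N)ccc2	2.279077
CNc1cccc2c1nc(Cl)cc2C(=O)N	2.331980
CSc1ccc2c(n1)c(C)cc(c2)F	2.314729
COc1cc2cc(cnc2cc1C)C(=O)N	2.038661
CNc1ccnc2c1c(F)cc(c2)SC	2.618991
Nc1ccc2c(c1)ncc(c2N)N	2.376078
CC[C@@H](c1cc2cc(SC)cnc2cc1C)C	2.895385
CNc1c(O)cc(c2c1cccn2)C(=O)N	2.440965
COc1ccc2c(c1F)cccn2	1.824237
CSc1cnc2c(c1N)cc(cc2)C(=O)N	2.416894
Clc1cc(O)c2c(c1)ccc(n2)F	2.398251
CC[C@@H](c1c(cnc2c1cccc2NC)C(=O)N)C	2.998443
CC[C@@H](c1cc(N)cc2c1c(N)ccn2)C	3.049085
CC[C@@H](c1c(ccc2c1cc(F)cn2)[C@H](CC)C)C	3.137713
CC[C@@H](c1nc2c(cc1Cl)cccc2C(=O)N)C	2.863397
CC[C@@H](c1cc2ccc(nc2cc1NC)SC)C	3.093808
CNc1ccc2c(c1)nc(c(c2)O)C	2.232405
CNc1cc2c(C)cccc2nc1C(=O)N	2.290775
Oc1ccc2c(c1)c(C)cc(n2)C(=O)N	2.115355
COc1c(F)cnc2c1c(O)ccc2	2.285741
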