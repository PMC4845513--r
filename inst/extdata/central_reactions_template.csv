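label,reaction_ids,description
1 hexokinase,FILL_IN,glucose -> G6P entry into glycolysis
2 phosphoglucose isomerase,FILL_IN,G6P <-> F6P
3 phosphofructokinase,FILL_IN,F6P -> FBP
4 aldolase,FILL_IN,FBP <-> DHAP + GAP
5 triose-phosphate isomerase,FILL_IN,DHAP <-> GAP
6 GAP dehydrogenase (NAD),FILL_IN,GAP <-> DPG
7 GAP dehydrogenase (NADP),FILL_IN,GAP -> 3-PGA (non-phosphorylating)
8 GAP dehydrogenase lumped,FILL_IN,sum of NAD/NADP routes
9 phosphoglycerate kinase,FILL_IN,DPG <-> 3-PGA
10 phosphoglycerate mutase,FILL_IN,3-PGA <-> 2-PGA
11 enolase,FILL_IN,2-PGA <-> PEP
12 pyruvate kinase,FILL_IN,PEP -> Pyr
13 pyruvate dehydrogenase,FILL_IN,Pyr -> AcCoA
14 citrate synthase,FILL_IN,AcCoA + OAA -> Cit
15 aconitase,FILL_IN,Cit <-> IsoCit
16 isocitrate dehydrogenase,FILL_IN,IsoCit -> 2-OG
17 2-OG dehydrogenase,FILL_IN,2-OG -> SucCoA
18 succinate thiokinase,FILL_IN,SucCoA <-> Suc
19 complex II,FILL_IN,Suc -> Fum
20 fumarase,FILL_IN,Fum <-> Mal
21 malate dehydrogenase,FILL_IN,Mal <-> OAA
22 G6P dehydrogenase,FILL_IN,G6P -> 6PGL (OPPP entry)
23 6-phosphogluconolactonase,FILL_IN,6PGL -> 6PG
24 6PG dehydrogenase,FILL_IN,6PG -> Ru5P
25 6PG dehydrogenase (alt),FILL_IN,alternative isozyme route
26 ribulose-phosphate 3-epimerase,FILL_IN,Ru5P <-> X5P
27 ribose-5-phosphate isomerase,FILL_IN,Ru5P <-> R5P
28 transketolase 1,FILL_IN,X5P + R5P <-> S7P + GAP
29 transketolase 2,FILL_IN,X5P + E4P <-> F6P + GAP
30 transaldolase,FILL_IN,S7P + GAP <-> E4P + F6P
31 PEP carboxylase,FILL_IN,PEP + CO2 -> OAA
32 complex I / NADH dehydrogenase,FILL_IN,ETC entry (lump alternative routes with ;)
33 complex IV / AOX,FILL_IN,terminal oxidases (lump with ;)
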