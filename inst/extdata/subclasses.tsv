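code	category	name
PA	glycerophospholipid	Phosphatidic acid
PC	glycerophospholipid	Phosphatidylcholine
PE	glycerophospholipid	Phosphatidylethanolamine
PG	glycerophospholipid	Phosphatidylglycerol
PI	glycerophospholipid	Phosphatidylinositol
PS	glycerophospholipid	Phosphatidylserine
CL	glycerophospholipid	Cardiolipin
LPA	glycerophospholipid	Lysophosphatidic acid
LPC	glycerophospholipid	Lysophosphatidylcholine
LPE	glycerophospholipid	Lysophosphatidylethanolamine
LPG	glycerophospholipid	Lysophosphatidylglycerol
LPI	glycerophospholipid	Lysophosphatidylinositol
LPS	glycerophospholipid	Lysophosphatidylserine
PIP	glycerophospholipid	Phosphatidylinositol phosphate
PIP2	glycerophospholipid	Phosphatidylinositol bisphosphate
PIP3	glycerophospholipid	Phosphatidylinositol trisphosphate
O-PA	glycerophospholipid	Ether phosphatidic acid
O-PC	glycerophospholipid	Ether phosphatidylcholine
O-PE	glycerophospholipid	Ether phosphatidylethanolamine
O-LPA	glycerophospholipid	Ether lysophosphatidic acid
O-LPC	glycerophospholipid	Ether lysophosphatidylcholine
O-LPE	glycerophospholipid	Ether lysophosphatidylethanolamine
MG	glycerolipid	Monoacylglycerol
DG	glycerolipid	Diacylglycerol
TG	glycerolipid	Triacylglycerol
O-MG	glycerolipid	Ether monoacylglycerol
O-DG	glycerolipid	Ether diacylglycerol
O-TG	glycerolipid	Ether triacylglycerol
SM	sphingolipid	Sphingomyelin
dhSM	sphingolipid	Dihydrosphingomyelin
Cer	sphingolipid	Ceramide
dhCer	sphingolipid	Dihydroceramide
Cer1P	sphingolipid	Ceramide-1-phosphate
dhCer1P	sphingolipid	Dihydroceramide-1-phosphate
Sph	sphingolipid	Sphingosine
dhSph	sphingolipid	Sphinganine
S1P	sphingolipid	Sphingosine-1-phosphate
dhS1P	sphingolipid	Sphinganine-1-phosphate
FA	fatty acyl	Fatty acid
FACoA	fatty acyl	Fatty acyl-CoA
CE	sterol	Cholesteryl ester
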