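# A priori panel of genes encoding enzymes of cholesterol homeostasis,
# assembled from the pathway diagrams of the brain cholesterol literature
# (pre-squalene mevalonate pathway, post-squalene Bloch/Kandutsch-Russell
# routes, enzymatic oxysterol formation, esterification). Editable
# configuration: the panel is not asserted to be exhaustive.
gene	pathway
ACAT1	de novo cholesterol biosynthesis (pre-squalene)
ACAT2	de novo cholesterol biosynthesis (pre-squalene)
HMGCS1	de novo cholesterol biosynthesis (pre-squalene)
HMGCR	de novo cholesterol biosynthesis (pre-squalene)
MVK	de novo cholesterol biosynthesis (pre-squalene)
PMVK	de novo cholesterol biosynthesis (pre-squalene)
IDI1	de novo cholesterol biosynthesis (pre-squalene)
IDI2	de novo cholesterol biosynthesis (pre-squalene)
FDPS	de novo cholesterol biosynthesis (pre-squalene)
GGPPS1	de novo cholesterol biosynthesis (pre-squalene)
FDFT1	de novo cholesterol biosynthesis (pre-squalene)
SQLE	de novo cholesterol biosynthesis (pre-squalene)
LSS	de novo cholesterol biosynthesis (pre-squalene)
DHCR24	de novo cholesterol biosynthesis (post-squalene)
CYP51A1	de novo cholesterol biosynthesis (post-squalene)
TM7SF2	de novo cholesterol biosynthesis (post-squalene)
SC4MOL	de novo cholesterol biosynthesis (post-squalene)
SC5D	de novo cholesterol biosynthesis (post-squalene)
DHCR7	de novo cholesterol biosynthesis (post-squalene)
CYP27A1	cholesterol catabolism (enzymatic)
CYP3A4	cholesterol catabolism (enzymatic)
CH25H	cholesterol catabolism (enzymatic)
CYP11A1	cholesterol catabolism (enzymatic)
CYP7B1	cholesterol catabolism (enzymatic)
CYP46A1	cholesterol catabolism (enzymatic)
CYP7A1	cholesterol catabolism (enzymatic)
CYP39A1	cholesterol catabolism (enzymatic)
CYP8B1	cholesterol catabolism (enzymatic)
HSD3B7	cholesterol catabolism (enzymatic)
SOAT1	cholesterol esterification
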