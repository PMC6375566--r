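# SYNTHETIC per-replicate GFP+ fold increases over vehicle for the 46-chemical library.
# Constructed example data: 19 chemicals exceed the BPA benchmark mean fold; mercury ranks first.
chemical,category,dose_uM,fold_rep1,fold_rep2,fold_rep3
mercury,crude-oil,10,6.045,5.633,5.752
thiabendazole,pesticide,100,5.705,5.069,3.986
benzene,crude-oil,100,4.552,4.587,4.51
triasulfuron,pesticide,100,3.987,4.038,4.514
xylene,crude-oil,100,3.676,4.156,3.778
DBP,phthalate,100,3.964,3.948,3.068
pendimethalin,pesticide,100,3.403,3.247,3.581
TCMTB,pesticide,10,2.67,3.6,3.571
permethrin,pesticide,100,2.544,3.429,3.176
DEHP,phthalate,100,2.86,2.65,3.011
piperonyl-butoxide,pesticide,100,3.202,2.318,2.46
BBP,phthalate,100,2.309,2.372,2.79
dicofol,pesticide,10,2.9,2.074,2.015
isopropanol,hydraulic-fracturing,100,2.473,1.885,2.272
DEP,phthalate,100,2.082,1.988,2.169
mancozeb,pesticide,10,1.8,2.131,1.98
ethylene-glycol,hydraulic-fracturing,100,1.678,1.99,1.913
parathion-methyl,pesticide,10,1.678,1.431,2.23
2-butoxyethanol,hydraulic-fracturing,100,1.968,1.553,1.578
BPA,plasticizer,100,1.67,1.483,1.706
phosalone,pesticide,10,1.591,1.653,1.407
pyridaben,pesticide,10,1.368,1.547,1.556
arsenic-oxide,pesticide,10,1.38,1.394,1.547
chlorpyrifos-methyl,pesticide,1,1.524,1.206,1.47
TCDD,dioxin,0.1,1.224,1.324,1.533
glyphosate,pesticide,100,1.358,1.276,1.326
atrazine,pesticide,100,1.53,1.337,0.974
malathion,pesticide,100,1.279,1.131,1.339
carbaryl,pesticide,100,0.973,1.494,1.194
naphthalene,crude-oil,100,1.139,1.262,1.168
toluene,crude-oil,100,1.139,1.135,1.205
ethylbenzene,crude-oil,100,1.247,1.027,1.115
methanol,hydraulic-fracturing,100,1.221,1.06,1.05
glutaraldehyde,hydraulic-fracturing,100,1.035,1.063,1.143
formaldehyde,hydraulic-fracturing,100,1.237,0.957,0.986
citric-acid,hydraulic-fracturing,100,0.931,1.047,1.141
polyacrylamide,hydraulic-fracturing,100,1.136,0.92,1.003
hydroxyethyl-cellulose,hydraulic-fracturing,100,0.987,0.884,1.16
DMP,phthalate,100,1.109,0.975,0.886
DiNP,phthalate,100,0.89,1.041,0.978
DNOP,phthalate,100,1.054,1.036,0.761
ethanol,hydraulic-fracturing,100,0.799,1.076,0.915
boric-acid,hydraulic-fracturing,100,0.932,1.021,0.778
sodium-persulfate,hydraulic-fracturing,100,0.909,0.892,0.9
potassium-chloride,hydraulic-fracturing,100,0.86,1.019,0.76
hexane,crude-oil,100,0.823,0.888,0.868
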