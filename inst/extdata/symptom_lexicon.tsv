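term	label
fever	objective
rash	objective
edema	objective
jaundice	objective
hepatomegaly	objective
splenomegaly	objective
lymphadenopathy	objective
clubbing	objective
cyanosis	objective
hematuria	objective
proteinuria	objective
elevated creatine kinase	objective
abnormal gait	objective
joint swelling	objective
contractures	objective
headache	subjective
dizziness	subjective
nausea	subjective
insomnia	subjective
anxiety	subjective
brain fog	subjective
numbness	subjective
tingling	subjective
generalized weakness	subjective
irritability	subjective
malaise	subjective
night sweats	subjective
poor appetite	subjective
memory loss	subjective
abdominal pain	subjective
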