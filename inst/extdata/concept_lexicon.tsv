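term	label
seizure	sign_or_symptom
ataxia	sign_or_symptom
hypotonia	sign_or_symptom
dysarthria	sign_or_symptom
tremor	sign_or_symptom
nystagmus	sign_or_symptom
dysphagia	sign_or_symptom
myalgia	sign_or_symptom
arthralgia	sign_or_symptom
vertigo	sign_or_symptom
syncope	sign_or_symptom
paresthesia	sign_or_symptom
pruritus	sign_or_symptom
dyspnea	sign_or_symptom
chronic pain	sign_or_symptom
muscle weakness	sign_or_symptom
developmental delay	sign_or_symptom
failure to thrive	sign_or_symptom
hearing loss	sign_or_symptom
vision loss	sign_or_symptom
spasticity	sign_or_symptom
neuropathy	sign_or_symptom
migraine	sign_or_symptom
apnea	sign_or_symptom
hyperreflexia	sign_or_symptom
mri	procedure
biopsy	procedure
electromyography	procedure
lumbar puncture	procedure
echocardiogram	procedure
endoscopy	procedure
karyotype	procedure
exome sequencing	procedure
genetic testing	procedure
complete blood count	procedure
metabolic panel	procedure
electroencephalogram	procedure
colonoscopy	procedure
nerve conduction study	procedure
ct scan	procedure
ultrasound	procedure
physical therapy	procedure
plasmapheresis	procedure
skin biopsy	procedure
muscle biopsy	procedure
epilepsy	disease_or_syndrome
mitochondrial disease	disease_or_syndrome
muscular dystrophy	disease_or_syndrome
lupus	disease_or_syndrome
juvenile arthritis	disease_or_syndrome
diabetes	disease_or_syndrome
cardiomyopathy	disease_or_syndrome
anemia	disease_or_syndrome
scoliosis	disease_or_syndrome
asthma	disease_or_syndrome
marfan syndrome	disease_or_syndrome
ehlers danlos syndrome	disease_or_syndrome
neurofibromatosis	disease_or_syndrome
leukodystrophy	disease_or_syndrome
myasthenia gravis	disease_or_syndrome
crohn disease	disease_or_syndrome
celiac disease	disease_or_syndrome
osteoporosis	disease_or_syndrome
dystonia	disease_or_syndrome
encephalopathy	disease_or_syndrome
cerebellum	body_part
spinal cord	body_part
liver	body_part
kidney	body_part
retina	body_part
cornea	body_part
femur	body_part
basal ganglia	body_part
brainstem	body_part
peripheral nerve	body_part
skeletal muscle	body_part
heart valve	body_part
aorta	body_part
thyroid	body_part
pancreas	body_part
bone marrow	body_part
white matter	body_part
optic nerve	body_part
hippocampus	body_part
left ventricle	body_part
pathogenic variant	gene_or_genome
de novo mutation	gene_or_genome
heterozygous	gene_or_genome
chromosome	gene_or_genome
microdeletion	gene_or_genome
duplication	gene_or_genome
missense variant	gene_or_genome
frameshift	gene_or_genome
mitochondrial dna	gene_or_genome
copy number variant	gene_or_genome
exon	gene_or_genome
autosomal recessive	gene_or_genome
x linked	gene_or_genome
trinucleotide repeat	gene_or_genome
candidate gene	gene_or_genome
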