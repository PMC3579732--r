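# Words ending in s that must not be singularised (mostly disease names,
# anatomical terms and mass nouns). Matching is case-insensitive.
diabetes
pertussis
measles
mumps
rabies
herpes
scabies
shingles
rickets
caries
aids
lupus
arthritis
hepatitis
psoriasis
sclerosis
cirrhosis
fibrosis
stenosis
thrombosis
osteoporosis
cystitis
dermatitis
gastritis
meningitis
nephritis
pancreatitis
bronchitis
colitis
sinusitis
uveitis
vasculitis
sepsis
asbestos
tetanus
typhus
species
series
feces
faeces
pubis
pelvis
testis
iris
mellitus
gravis
biceps
forceps
news
pons
lens
vas
plus
versus
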