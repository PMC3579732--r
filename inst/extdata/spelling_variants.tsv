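word	variant
anaemia	anemia
anaemic	anemic
anaesthesia	anesthesia
anaesthetic	anesthetic
analyse	analyze
analysed	analyzed
analyser	analyzer
analysing	analyzing
behaviour	behavior
behavioural	behavioral
caecum	cecum
caesarean	cesarean
cancelled	canceled
catalogue	catalog
centre	center
centred	centered
characterise	characterize
characterised	characterized
coeliac	celiac
colour	color
coloured	colored
colouring	coloring
counselling	counseling
defence	defense
diarrhoea	diarrhea
dyspnoea	dyspnea
faeces	feces
faecal	fecal
favour	favor
favourable	favorable
fibre	fiber
foetal	fetal
foetus	fetus
fulfil	fulfill
goitre	goiter
gonorrhoea	gonorrhea
gynaecology	gynecology
gynaecological	gynecological
haematology	hematology
haematological	hematological
haematocrit	hematocrit
haematoma	hematoma
haematuria	hematuria
haemoglobin	hemoglobin
haemolysis	hemolysis
haemolytic	hemolytic
haemophilia	hemophilia
haemorrhage	hemorrhage
haemorrhagic	hemorrhagic
haemorrhoid	hemorrhoid
haemostasis	hemostasis
homologue	homolog
hypopnoea	hypopnea
immunise	immunize
immunisation	immunization
ionised	ionized
ischaemia	ischemia
ischaemic	ischemic
jewellery	jewelry
labelled	labeled
labelling	labeling
labour	labor
leucocyte	leukocyte
leukaemia	leukemia
leukaemic	leukemic
litre	liter
localisation	localization
localised	localized
metabolise	metabolize
metre	meter
microlitre	microliter
millilitre	milliliter
millimetre	millimeter
minimise	minimize
modelled	modeled
modelling	modeling
mould	mold
neighbour	neighbor
neighbourhood	neighborhood
normalisation	normalization
normalise	normalize
normalised	normalized
odour	odor
oedema	edema
oedematous	edematous
oesophageal	esophageal
oesophagitis	esophagitis
oesophagus	esophagus
oestradiol	estradiol
oestrogen	estrogen
oestrus	estrus
organisation	organization
organise	organize
organised	organized
orthopaedic	orthopedic
paediatric	pediatric
paediatrics	pediatrics
paralyse	paralyze
paralysed	paralyzed
practise	practice
programme	program
randomisation	randomization
randomise	randomize
randomised	randomized
recognise	recognize
recognised	recognized
rumour	rumor
sensitisation	sensitization
sensitise	sensitize
sensitised	sensitized
signalling	signaling
standardisation	standardization
standardise	standardize
standardised	standardized
sulphate	sulfate
sulphide	sulfide
sulphur	sulfur
theatre	theater
titre	titer
tonne	ton
travelled	traveled
travelling	traveling
tumour	tumor
tumourigenesis	tumorigenesis
utilisation	utilization
utilise	utilize
utilised	utilized
vapour	vapor
vigour	vigor
visualisation	visualization
visualise	visualize
visualised	visualized
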