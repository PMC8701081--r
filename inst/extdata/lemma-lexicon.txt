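analyses analysis
bases basis
crises crisis
diagnoses diagnosis
hypotheses hypothesis
prognoses prognosis
theses thesis
children child
men man
women woman
mice mouse
feet foot
teeth tooth
criteria criterion
phenomena phenomenon
bacteria bacterium
media medium
genera genus
fungi fungus
nuclei nucleus
stimuli stimulus
foci focus
loci locus
indices index
matrices matrix
appendices appendix
vertebrae vertebra
larvae larva
antennae antenna
sera serum
genomes genome
viruses virus
coronaviruses coronavirus
vaccines vaccine
antibodies antibody
studies study
countries country
therapies therapy
strategies strategy
studied study
better good
best good
worse bad
worst bad
people person
data data
series series
species species
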