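group	keyword
visual system	visual
visual system	eye
visual system	photoreceptor
visual system	retina
reproduction	reproduct
reproduction	sperm
reproduction	oocyte
DNA damage response	dna repair
DNA damage response	dna damage
proteolysis	proteolysis
proteolysis	peptidase
lipid metabolism	lipid
lipid metabolism	fatty acid
neural processes	nervous system
neural processes	neuron
neural processes	synap
olfaction	olfactory
olfaction	smell
immunity	immune
immunity	defense response
circadian	circadian
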