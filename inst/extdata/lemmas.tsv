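form	lemma
increased	increase
increases	increase
increasing	increase
decreased	decrease
decreases	decrease
decreasing	decrease
elevated	elevate
swollen	swell
swelling	swell
levels	level
enzymes	enzyme
arms	arm
legs	leg
eyes	eye
feet	foot
teeth	tooth
children	child
men	man
women	woman
itching	itch
bleeding	bleed
vomiting	vomit
worsening	worsen
reduced	reduce
impaired	impair
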