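name	formula	delta_mass	targets	position_rule	lability
myristoyl	C14H26O		C	anywhere	thioester_acyl
palmitoyl	C16H30O		C	anywhere	thioester_acyl
stearoyl	C18H34O		C	anywhere	thioester_acyl
farnesyl	C15H24		C	anywhere	thioether_prenyl
geranylgeranyl	C20H32		C	anywhere	thioether_prenyl
NEM	C6H7NO2		C	anywhere	stable
carbamidomethyl	C2H3NO		C	anywhere	stable
acetyl-protein-N-term	C2H2O		*	protein-N-term	stable
oxidation-M	O		M	anywhere	stable
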