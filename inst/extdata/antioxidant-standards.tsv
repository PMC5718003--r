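name	formula
gentisic acid	C7H6O4
gallic acid	C7H6O5
caffeic acid	C9H8O4
luteolin	C15H10O6
kaempferol	C15H10O6
quercetin	C15H10O7
dihydroquercetin	C15H12O7
chlorogenic acid	C16H18O9
quercitrin	C21H20O11
quercetin-3-o-glucoside	C21H20O12
rutin	C27H30O16
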