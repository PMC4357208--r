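# Measured phenotype and resolution bounds for exponential growth on glucose
# minimal medium (host and transformant are macroscopically indistinguishable).
mu: 0.2                # specific growth rate, 1/h
yxs_low: 0.39          # biomass yield on glucose, g cell / g glucose
yxs_high: 0.45
yxatp_low: 7.0         # biomass yield on ATP, g cell / mol ATP
yxatp_high: 10.0
acetate_mode: tight    # "tight": r_ACE fixed at acetate; "loose": range below
acetate: 1.0           # mmol / g cell h
acetate_low: 0.8
acetate_high: 1.2
lactate: 0.0           # mmol / g cell h (none detected)
po_nadh: 2.0           # ATP per NADH oxidized
po_fadh: 1.0           # ATP per FADH2 oxidized
glucose_mw: 180        # g/mol, for yield <-> flux conversion
dna_load_factor: 1.0   # multiplier on DNA-attributable precursor loads
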