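# The nine chapters of the ICF Activities and Participation component
# (published chapter list; titles as printed).
code	kind	title
d1	chapter	Learning and applying knowledge
d2	chapter	General tasks and demands
d3	chapter	Communication
d4	chapter	Mobility
d5	chapter	Self-care
d6	chapter	Domestic life
d7	chapter	Interpersonal interactions and relationships
d8	chapter	Major life areas
d9	chapter	Community, social and civic life
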