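# Block- and category-level mappings to SUMO stated in the published
# analysis prose (the full 11-block / 22-category / 21-subcategory mapping
# exists only graphically and is not encoded here).
source_code	target_concept	match_kind	note
d160-d179	IntentionalPsychologicalProcess	broader	Applying knowledge block, mapped as a whole
d310-d329	Interpreting	broader	better a superclass of Interpreting over a generic ContentBearingObject
d330-d349	ContentDevelopment	partial	mapped with some doubts
d350-d369	Communication	broader	conversation incl. communication devices
d170	Writing	equivalent
d172	Calculating	equivalent
d540	Dressing	equivalent
d550	Eating	equivalent
d560	Drinking	equivalent
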