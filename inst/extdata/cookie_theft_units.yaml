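# Content-unit checklist for the Cookie Theft picture description.
# Each entry maps a unit identifier to one or more trigger patterns; a
# pattern is a space-separated sequence of lemmas that must occur
# contiguously in the non-maze lemma sequence of one C-unit. A unit counts
# at most once per sample no matter how often it is mentioned.
boy: [boy, son, brother]
girl: [girl, daughter, sister]
woman: [woman, mother, mom, lady]
kitchen: [kitchen]
cookie: [cookie, cookies]
jar: [jar, "cookie jar"]
stool: [stool, chair, ladder]
sink: [sink, basin]
plate: [plate, dish, dishes]
water: [water]
window: [window]
curtains: [curtain, curtains]
counter: [counter, counters]
exterior: [outside, yard, garden, sidewalk, driveway]
boy_taking_cookie: ["take cookie", "steal cookie", "get cookie", "grab cookie"]
boy_on_stool: ["on stool", "on the stool", "climb stool"]
stool_falling: ["stool fall", "stool tip", "stool wobble", "fall off", "tip over"]
girl_reaching: ["reach up", "reach for", "hold hand", "put finger"]
woman_washing: ["wash dish", "wash dishes", "wash plate", "do dishes"]
woman_drying: ["dry dish", "dry dishes", "dry plate"]
water_overflowing: ["water overflow", "sink overflow", "water run", "run over", "spill over"]
woman_unaware: [ignore, unaware, oblivious, daydream, "not notice", "not pay attention"]
asking_for_cookie: ["ask for", "want cookie", "shush", "quiet"]
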