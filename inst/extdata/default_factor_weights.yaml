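# Default factor configuration: measure loadings, per-factor sign flips,
# and (empty) reference standardization constants to be filled by
# calibrate_reference() on a reference sample.
#
# Loadings use equal unit magnitudes within each factor; their signs
# encode the raw direction of each measure inside the construct (the
# Semantic construct loads positively on pronoun use and verb proportion
# and negatively on noun proportion). The Semantic and Fluency factors
# are then multiplied by -1 so that, for every factor, higher scores mean
# better performance. True loadings estimated from a factor analysis can
# be dropped in via this file.
loadings:
  Semantic:
    percent_nouns: -1.0
    percent_verbs: 1.0
    pronoun_index: 1.0
  Syntax:
    verb_index: 1.0
    proposition_density: 1.0
    grammatical_complexity: 1.0
  Lexical:
    type_token_ratio: 1.0
    unique_words: 1.0
    semantic_unit_count: 1.0
  Fluency:
    maze_index: 1.0
sign_flip:
  Semantic: -1
  Syntax: 1
  Lexical: 1
  Fluency: -1
reference_means: {}
reference_sds: {}
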