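# Editable phrase lists for free-text phenotype matching
# (case-insensitive substring search; see ?match_phenotype_terms).
intellectual_disability:
  - intellectual disability
  - mental retardation
  - cognitive impairment
  - global developmental delay
seizures:
  - seizures
  - epilepsy
  - epileptic encephalopathy
  - infantile spasms
language:
  - impaired language development
  - language delay
  - absent speech
  - speech delay
motor:
  - impaired motor development
  - motor delay
  - delayed walking
spasticity:
  - spasticity
  - spastic paraplegia
  - spastic tetraplegia
ataxia:
  - ataxia
  - gait ataxia
  - cerebellar atrophy
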