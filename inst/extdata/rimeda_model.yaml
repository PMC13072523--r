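# Canonical 13-entity re-identification risk model.
#
# Entity scheme, perspectives, weight domains and the D1/TO2 doubling flags
# follow the published system. The influence-matrix cell values in
# rimeda_matrix_synthetic.csv are a SYNTHETIC STAND-IN: the original
# prototype workbook's transcription is not redistributable, so the cells
# were curated once from the published qualitative descriptions of the
# inter-entity relationships (strong/medium/weak, parallel/opposing).
# Absolute scores from this model are therefore illustrative; the model
# structure and qualitative lever behaviour follow the published system.
id: rimeda-canonical-synthetic
weighting_strategy: row
q_convention: active_sign
perspectives:
  - id: D
    name: Data
    description: >-
      Properties derivable from the dataset itself by mathematical means,
      plus particularly risky quasi-identifier combinations.
  - id: W
    name: Knowledge
    description: >-
      Additional knowledge an adversary can link against the released data;
      inherently fuzzy to operationalise.
  - id: A
    name: Attacker
    description: >-
      The potential adversary's disposition and capabilities.
  - id: TO
    name: Technical/organisational
    description: >-
      Environmental safeguards of the releasing organisation; the
      perspective through which risk can be actively reduced (negative
      weighting admissible).
entities:
  - id: D1
    name: Uniqueness
    perspective: D
    weight_domain: [0, 1, 2, 3]
    double: true
    controllable: true
    rubric:
      - "Attribute: proportion of unique records among the total number of records (0%-100%)."
      - "0 = no unique records; 3 = a large share of records is unique."
    countermeasures:
      - "Generalise quasi-identifying attributes (coarser categories, wider intervals)."
      - "Suppress rare attribute values or whole outlier records."
      - "Enforce k-anonymity style grouping before release."
  - id: D2
    name: Similarity
    perspective: D
    weight_domain: [0, 1, 2, 3]
    double: false
    controllable: true
    rubric:
      - "Attribute: number of similar records (0%-100% of the dataset)."
      - "0 = records indistinguishable in large groups; 3 = hardly any record has close neighbours."
    countermeasures:
      - "Aggregate or microaggregate records to enlarge similarity groups."
      - "Randomise (perturb) attribute values to blur record-level distinctions."
  - id: D3
    name: Vulnerable quasi-identifier
    perspective: D
    weight_domain: [0, 1, 2, 3]
    double: false
    controllable: true
    rubric:
      - "Attributes: length of stay, treating physician, diagnosis, date of admission, date of birth, sex, zip code - included in the dataset or not."
      - "0 = none of the vulnerable combinations included; 3 = several included in full precision."
    countermeasures:
      - "Suppress or coarsen the listed quasi-identifiers (year instead of date, region instead of zip code)."
      - "Release only the attributes strictly needed for the research purpose."
  - id: W1
    name: External data sources
    perspective: W
    weight_domain: [1, 2, 3]
    double: false
    controllable: false
    rubric:
      - "Attributes: type (undetermined), suitability (unsuitable/suitable), availability (low/medium/high)."
      - "1 = hardly any suitable linkable source; 3 = suitable sources readily available."
    countermeasures:
      - "Monitor the registry/open-data landscape for linkable sources before release."
  - id: W2
    name: Background/contextual information
    perspective: W
    weight_domain: [1, 2, 3]
    double: false
    controllable: false
    rubric:
      - "Attributes: type, suitability, availability of contextual knowledge (press coverage, social media, local knowledge)."
      - "1 = little exploitable context; 3 = rich, public context."
    countermeasures:
      - "Assess the publicity of the cohort (rare diseases, public figures) before release."
  - id: W3
    name: Metadata
    perspective: W
    weight_domain: [0, 1, 2, 3]
    double: false
    controllable: false
    rubric:
      - "Attributes: type, suitability, availability of metadata accompanying the release."
      - "0 = no metadata released; 3 = rich metadata with high linkage value."
    countermeasures:
      - "Strip technical and administrative metadata from exports."
      - "Review codebooks and documentation for identifying detail."
  - id: W4
    name: Data inference
    perspective: W
    weight_domain: [1, 2, 3]
    double: false
    controllable: false
    rubric:
      - "Attribute: inference potential (low/medium/high) - what can be deduced from attribute combinations."
      - "1 = little deducible; 3 = sensitive facts readily deducible."
    countermeasures:
      - "Evaluate deducibility of sensitive attributes from released combinations."
  - id: A1
    name: Motivation
    perspective: A
    weight_domain: [1, 2, 3]
    double: false
    controllable: false
    rubric:
      - "Attribute: degree (low/medium/high) of an adversary's incentive to re-identify."
    countermeasures:
      - "Bind recipients by data use agreements and sanctions."
  - id: A2
    name: Skills
    perspective: A
    weight_domain: [1, 2, 3]
    double: false
    controllable: false
    rubric:
      - "Attribute: degree (low/medium/high) of adversary capability."
    countermeasures:
      - "Assume state-of-the-art linkage capability for open releases."
  - id: A3
    name: Resources
    perspective: A
    weight_domain: [1, 2, 3]
    double: false
    controllable: false
    rubric:
      - "Attribute: degree (low/medium/high) of adversary resources (compute, money, time)."
    countermeasures:
      - "Raise the cost of attack through access control and contractual barriers."
  - id: TO1
    name: Awareness
    perspective: TO
    weight_domain: [-3, 1, 2, 3]
    double: false
    controllable: true
    rubric:
      - "Attributes: degree and degree of implementation (low/medium/high) of organisational risk awareness."
      - "-3 = strongly developed awareness actively reducing risk; 3 = awareness absent."
    countermeasures:
      - "Train staff; institutionalise release review boards."
  - id: TO2
    name: Methods
    perspective: TO
    weight_domain: [-3, 1, 2, 3]
    double: true
    controllable: true
    rubric:
      - "Attributes: type and quality (low/medium/high) of the anonymisation/pseudonymisation methods applied."
      - "-3 = high-quality methods strongly inhibiting re-identification; 3 = no or poor methods."
    countermeasures:
      - "Apply generalisation, suppression and randomisation before release."
      - "Validate the anonymisation with established tooling."
  - id: TO3
    name: Data security
    perspective: TO
    weight_domain: [-3, 1, 2, 3]
    double: false
    controllable: true
    rubric:
      - "Attribute: degree of implementation (low/medium/high) of technical data security."
      - "-3 = strong technical protection; 3 = weak protection."
    countermeasures:
      - "Encrypt at rest and in transit; log and restrict access."
matrix:
  csv: rimeda_matrix_synthetic.csv
bands:
  mode: equal_width
  n_bands: 4
  labels: [low, moderate, high, critical]
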