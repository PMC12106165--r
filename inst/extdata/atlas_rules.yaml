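# Default morphological-atlas rules: declarative mapping from region-level
# pathological changes (plus optional parameter predicates) to disease labels.
#
# A rule fires when every `requires` (region, change) pair matches an
# unconsumed finding and every `where` predicate holds on the morphometry
# report.  Rules are applied in descending priority; a fired rule consumes the
# findings it matched, so the composite BPES rule subsumes its component
# rules (blepharoptosis, epicanthus inversus) instead of co-reporting them.
# `region: any` matches a change in any admissible region.
version: 1
rules:
- disease: BPES
  priority: 10
  requires:
  - {region: upper_eyelid, change: ptosis}
  - {region: inner_canthus, change: epicanthus_inversus}
  where:
  - {param: icd_mm, op: lt, value: 30.0}
- disease: blepharoptosis
  priority: 1
  requires:
  - {region: upper_eyelid, change: ptosis}
- disease: thyroid-associated ophthalmopathy
  priority: 1
  requires:
  - {region: upper_eyelid, change: upper_retraction}
- disease: thyroid-associated ophthalmopathy
  priority: 1
  requires:
  - {region: lower_eyelid, change: lower_retraction}
- disease: entropion and trichiasis
  priority: 1
  requires:
  - {region: any, change: entropion_trichiasis}
- disease: ectropion
  priority: 1
  requires:
  - {region: lower_eyelid, change: ectropion}
- disease: eyelid tumor
  priority: 1
  requires:
  - {region: any, change: tumor}
- disease: epicanthus inversus
  priority: 1
  requires:
  - {region: inner_canthus, change: epicanthus_inversus}
- disease: other types of epicanthus
  priority: 1
  requires:
  - {region: inner_canthus, change: epicanthus_other}
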