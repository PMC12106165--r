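# Parameter templates for the synthetic scene generator.
#
# Ranges [lo, hi] are sampled uniformly per scene; scalars are fixed.  Units:
# *_mm in millimetres, *_px in pixels.  mrd1_mm / mrd2_mm are the *target
# truth* margin reflex distances at the corneal axis; the generator solves the
# lid-curve extrema so the rendered geometry attains them exactly.
#
# Defaults model the study conditions: a standardised frontal close-up at
# 0.2 mm/px (a ~64 x 44 mm field), adult inter-canthal (horizontal fissure)
# length 28-31 mm, corneal radius 5.5 mm, a 10-mm forehead marker, and mild
# sensor noise (sd 0.02 on unit intensities).  Disease templates place the
# defining parameter comfortably beyond its screening threshold (ptosis
# MRD1 < 2 mm, upper retraction MRD1 > 5 mm, lower retraction MRD2 > 5.5 mm,
# BPES inter-canthal distance < 30 mm) so the class predicate holds for every
# jitter draw.
version: 1
defaults:
  image_size: [220, 320]
  mm_per_px: 0.2
  chord_y_px: 140
  cornea_radius_mm: 5.5
  marker_center_px: [160, 40]
  marker_diameter_mm: 10
  noise_sd: 0.02
  icd_mm: [28.0, 31.0]
  mrd1_mm: [3.0, 4.2]
  mrd2_mm: [2.0, 2.8]
  cornea_dx_mm: [-0.6, 0.6]
  cornea_dy_mm: [-0.4, 0.4]
  chord_jitter_mm: [-0.6, 0.6]
conditions:
  normal: {}
  blepharoptosis:
    mrd1_mm: [0.8, 1.6]
  thyroid-associated ophthalmopathy:
    mrd1_mm: [5.6, 6.8]
  lower eyelid retraction:
    mrd2_mm: [6.0, 7.0]
  entropion and trichiasis:
    trichiasis: true
  ectropion:
    ectropion: true
  eyelid tumor:
    tumor_radius_mm: [1.2, 2.2]
  epicanthus inversus:
    fold: epicanthus_inversus
    fold_extent_mm: [2.5, 4.0]
  other types of epicanthus:
    fold: epicanthus_other
    fold_extent_mm: [2.5, 4.0]
  BPES:
    mrd1_mm: [0.8, 1.6]
    icd_mm: [20.0, 24.0]
    fold: epicanthus_inversus
    fold_extent_mm: [2.5, 4.0]
  blepharoptosis + trichiasis:
    mrd1_mm: [0.8, 1.6]
    trichiasis: true
  blepharoptosis + other types of epicanthus:
    mrd1_mm: [0.8, 1.6]
    fold: epicanthus_other
    fold_extent_mm: [2.5, 4.0]
  blepharoptosis + ectropion:
    mrd1_mm: [0.8, 1.6]
    ectropion: true
aliases:
  ptosis: blepharoptosis
  TAO: thyroid-associated ophthalmopathy
  upper eyelid retraction: thyroid-associated ophthalmopathy
  tumor: eyelid tumor
  lower eyelid ectropion: ectropion
  eyelid entropion and trichiasis: entropion and trichiasis
  entropion: entropion and trichiasis
  trichiasis: entropion and trichiasis
  blepharophimosis/ptosis/epicanthus inversus syndrome: BPES
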