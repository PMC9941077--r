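name: modified-zhang-12
description: >
  Twelve-item corneal wound-closure quality rubric, each item rated on a
  5-point scale (total 12-60). Derived from the 15-item Zhang corneal
  suturing scale with the preoperative-preparation, postoperative-clean-up
  and knot-rotation items removed.
scale_min: 1
scale_max: 5
items:
  - needle_holding_and_loading
  - needle_entry_perpendicularity
  - needle_passage_depth
  - bite_symmetry_across_wound
  - stitch_1_completion
  - stitch_2_completion
  - stitch_3_completion
  - fluency_of_movements
  - economy_of_time
  - stitch_geometry_regularity
  - knot_security
  - wound_closure_efficacy
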