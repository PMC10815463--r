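# Variant of sti_discharge.yaml in which the root row supports all eight
# diseases except SP and HSV (i.e. AW included), following the prose
# description of the worked example rather than the printed row marks.
registry:
- {code: BV, label: bacterial vaginosis, group: sexually_transmitted_infections}
- {code: TM, label: trichomoniasis, group: sexually_transmitted_infections}
- {code: VC, label: vulva candidiasis, group: sexually_transmitted_infections}
- {code: SP, label: syphilis, group: sexually_transmitted_infections}
- {code: NG, label: neisseria gonorrhoeae, group: sexually_transmitted_infections}
- {code: CM, label: chlamydia, group: sexually_transmitted_infections}
- {code: HSV, label: herpes simplex virus ii, group: sexually_transmitted_infections}
- {code: AW, label: anogenital warts, group: sexually_transmitted_infections}
tables:
- id: sti_discharge
  trigger: vaginal_discharge
  columns: [BV, TM, VC, SP, NG, CM, HSV, AW]
  rows:
  - id: r1
    adds: [vaginal_discharge]
    select: [BV, TM, VC, NG, CM, AW]
  - id: r2
    parent: r1
    adds: ["quantity(vd,profuse)", "texture(vd,thin)", "colour(vd,green)"]
    select: [BV, TM, NG]
  - id: r3
    parent: r2
    adds: ["texture(vd,frothy)"]
    select: [BV, TM]
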