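# Diagnostic table for the presenting complaint "burning and/or itching":
# adding inter-menstrual or post-coital bleeding, and then cauliflower-shaped
# lumps (or a condyloma image), narrows the verdict down to anogenital warts.
registry:
- {code: BV, label: bacterial vaginosis, group: sexually_transmitted_infections}
- {code: TM, label: trichomoniasis, group: sexually_transmitted_infections}
- {code: VC, label: vulva candidiasis, group: sexually_transmitted_infections}
- {code: SP, label: syphilis, group: sexually_transmitted_infections}
- {code: NG, label: neisseria gonorrhoeae, group: sexually_transmitted_infections}
- {code: CM, label: chlamydia, group: sexually_transmitted_infections}
- {code: HSV, label: herpes simplex virus ii, group: sexually_transmitted_infections}
- {code: AW, label: anogenital warts, group: sexually_transmitted_infections}
- {code: HIV, label: human immunodeficiency virus, group: sexually_transmitted_infections}
tables:
- id: sti_burning
  trigger: burning +/ itching
  columns: [BV, TM, VC, SP, NG, CM, HSV, AW, HIV]
  rows:
  - id: r1
    adds: ["burning +/ itching"]
    select: [BV, TM, VC, NG, CM, HSV, AW]
  - id: r2
    parent: r1
    adds: ["intermenstrual_bleeding +/ postcoital_bleeding"]
    select: [VC, NG, CM, AW]
  - id: r3
    parent: r2
    adds: ["lumps(small_cauliflower) +/ image(2,condyloma)"]
    select: [AW]
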