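# Default disease registry: the named diseases of the seven gynaecological
# presentation groups.  Vulva cancer, listed under both cancer and vulva
# pathology, appears once (under vulva_pathology) because codes are unique.
registry:
- {code: CP, label: colonic polyps, group: bleeding}
- {code: ENP, label: endometrial polyps, group: bleeding}
- {code: MC, label: miscarriage, group: bleeding}
- {code: PA, label: placenta abruption, group: bleeding}
- {code: PPR, label: placenta previa, group: bleeding}
- {code: CER, label: cervical erosion, group: bleeding}
- {code: CUS, label: cushing syndrome, group: endocrinology}
- {code: ADT, label: adrenal tumour, group: endocrinology}
- {code: DPU, label: delayed puberty, group: endocrinology}
- {code: MRKS, label: mayer-rokitansky-kuster-hauser syndrome, group: endocrinology}
- {code: CCA, label: cervical cancer, group: cancer}
- {code: ECA, label: endometrial cancer, group: cancer}
- {code: OCA, label: ovarian cancer, group: cancer}
- {code: VAC, label: vaginal cancer, group: cancer}
- {code: APX, label: appendicitis, group: pelvic_pain}
- {code: ECP, label: ectopic pregnancy, group: pelvic_pain}
- {code: ADH, label: adhesions, group: pelvic_pain}
- {code: DIV, label: diverticulitis, group: pelvic_pain}
- {code: OCR, label: ovarian cyst rupture, group: pelvic_pain}
- {code: OT, label: ovarian torsion, group: pelvic_pain}
- {code: RCL, label: ruptured corpus luteum, group: pelvic_pain}
- {code: ADM, label: adenomyosis, group: pelvic_pain}
- {code: MAO, label: mesenteric artery occlusion, group: pelvic_pain}
- {code: EM, label: endometriosis, group: pelvic_pain}
- {code: ROF, label: ruptured ovarian follicles, group: pelvic_pain}
- {code: FIB, label: fibroids, group: pelvic_pain}
- {code: FTT, label: fallopian tube torsion, group: pelvic_pain}
- {code: LM, label: leiomyoma, group: pelvic_pain}
- {code: ANT, label: adnexal tumour, group: pelvic_pain}
- {code: BI, label: bowel infection, group: pelvic_pain}
- {code: BO, label: bowel obstruction, group: pelvic_pain}
- {code: NL, label: nephrolithiasis, group: urogynaecology}
- {code: PN, label: pyelonephritis, group: urogynaecology}
- {code: AW, label: anogenital warts, group: sexually_transmitted_infections}
- {code: BV, label: bacterial vaginosis, group: sexually_transmitted_infections}
- {code: HP, label: hepatitis, group: sexually_transmitted_infections}
- {code: CM, label: chlamydia, group: sexually_transmitted_infections}
- {code: TM, label: trichomoniasis, group: sexually_transmitted_infections}
- {code: VC, label: vulva candidiasis, group: sexually_transmitted_infections}
- {code: NG, label: neisseria gonorrhoeae, group: sexually_transmitted_infections}
- {code: SP, label: syphilis, group: sexually_transmitted_infections}
- {code: HSV, label: herpes simplex virus ii, group: sexually_transmitted_infections}
- {code: HIV, label: human immunodeficiency virus, group: sexually_transmitted_infections}
- {code: VIN, label: vulva intraepithelial neoplasia, group: vulva_pathology}
- {code: VUC, label: vulva cancer, group: vulva_pathology}
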