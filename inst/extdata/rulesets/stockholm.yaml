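# Stockholm MRI grading, APPROXIMATE reconstruction.
# The original tier definitions are not reproduced here; this rule set
# encodes only what is stated about the system in the comparison study:
# thalamic TAI is incorporated, bilateral TAI in pons is the worst grade,
# grades 2-3 span more sublocations than the standard grading, and patients
# without TAI are not distinguished from hemispheric TAI (both grade 1).
# Review against the original publication before any comparative claim.
name: stockholm
no_tai_grade: 1
rules:
  - grade: 1
    when: "tai_hemispheric || tai_cerebellum"
  - grade: 2
    when: "tai_corpus_callosum || tai_internal_capsule_pl_uni || tai_internal_capsule_pl_bil || tai_basal_ganglia_uni || tai_basal_ganglia_bil"
  - grade: 3
    when: "tai_thalamus_uni || tai_thalamus_bil || tai_mesencephalon_uni || tai_mesencephalon_bil || tai_pons_uni || tai_medulla_uni || tai_medulla_bil || tai_cerebellar_peduncle_uni || tai_cerebellar_peduncle_bil"
  - grade: 4
    when: "tai_pons_bil"
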