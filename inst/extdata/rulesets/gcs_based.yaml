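# Injury-severity (GCS-based) TAI-MRI grading, APPROXIMATE reconstruction.
# Encodes the one stated property of the system: bilateral TAI in the
# brainstem or thalami is the worst grade. Lower tiers follow the standard
# grading shape with deep unilateral lesions as grade 3.
# Review against the original publication before any comparative claim.
name: gcs_based
no_tai_grade: 0
rules:
  - grade: 1
    when: "tai_hemispheric || tai_cerebellum"
  - grade: 2
    when: "tai_corpus_callosum || tai_internal_capsule_pl_uni || tai_internal_capsule_pl_bil"
  - grade: 3
    when: "tai_thalamus_uni || tai_mesencephalon_uni || tai_pons_uni || tai_medulla_uni || tai_cerebellar_peduncle_uni || tai_cerebellar_peduncle_bil || tai_basal_ganglia_uni || tai_basal_ganglia_bil"
  - grade: 4
    when: "tai_brainstem_bil || tai_thalamus_bil"
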