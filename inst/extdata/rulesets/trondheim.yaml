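# Trondheim TAI-MRI grading (grades 0-5).
# Final grade = highest rule whose predicate holds; 0 if no TAI anywhere.
# Predicates are R expressions over the named region-feature flags.
name: trondheim
no_tai_grade: 0
rules:
  - grade: 1
    when: "tai_hemispheric || tai_cerebellum"
  - grade: 2
    when: "tai_corpus_callosum"
  # Unilateral thalamus or brainstem (incl. cerebellar peduncles) or any
  # basal-ganglia TAI. Cerebellar peduncles count towards grade 3 only:
  # they never trigger grades 4-5 without parenchymal involvement.
  - grade: 3
    when: "tai_thalamus_uni || tai_mesencephalon_uni || tai_pons_uni || tai_medulla_uni || tai_cerebellar_peduncle_uni || tai_cerebellar_peduncle_bil || tai_basal_ganglia_uni || tai_basal_ganglia_bil"
  # Bilateral mesencephalon or thalami; bilateral medulla (not addressed in
  # the source grading) defaults to the bilateral non-pons brainstem tier.
  - grade: 4
    when: "tai_mesencephalon_bil || tai_thalamus_bil || tai_medulla_bil"
  - grade: 5
    when: "tai_pons_bil"
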