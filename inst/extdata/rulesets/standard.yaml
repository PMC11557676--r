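# Standard (Gentry/Adams) three-grade TAI grading.
# Grade 1 hemispheres (incl. cerebellum); grade 2 corpus callosum;
# grade 3 brainstem (incl. cerebellar peduncles). No TAI = grade 0.
name: standard
no_tai_grade: 0
rules:
  - grade: 1
    when: "tai_hemispheric || tai_cerebellum"
  - grade: 2
    when: "tai_corpus_callosum"
  - grade: 3
    when: "tai_brainstem_any || tai_cerebellar_peduncle_uni || tai_cerebellar_peduncle_bil"
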