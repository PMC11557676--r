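code,region_group,side
cc_genu,corpus_callosum,midline
cc_truncus,corpus_callosum,midline
cc_splenium,corpus_callosum,midline
cerebellar_vermis,cerebellum,midline
frontal_wm,hemispheric_wm,left
frontal_wm,hemispheric_wm,right
temporal_wm,hemispheric_wm,left
temporal_wm,hemispheric_wm,right
parietal_wm,hemispheric_wm,left
parietal_wm,hemispheric_wm,right
occipital_wm,hemispheric_wm,left
occipital_wm,hemispheric_wm,right
insular_wm,hemispheric_wm,left
insular_wm,hemispheric_wm,right
centrum_semiovale,hemispheric_wm,left
centrum_semiovale,hemispheric_wm,right
corona_radiata,hemispheric_wm,left
corona_radiata,hemispheric_wm,right
cingulum,hemispheric_wm,left
cingulum,hemispheric_wm,right
external_capsule,hemispheric_wm,left
external_capsule,hemispheric_wm,right
internal_capsule_al,hemispheric_wm,left
internal_capsule_al,hemispheric_wm,right
gray_white_junction,hemispheric_wm,left
gray_white_junction,hemispheric_wm,right
hippocampus,hemispheric_wm,left
hippocampus,hemispheric_wm,right
internal_capsule_pl,internal_capsule_pl,left
internal_capsule_pl,internal_capsule_pl,right
caudate,basal_ganglia,left
caudate,basal_ganglia,right
putamen,basal_ganglia,left
putamen,basal_ganglia,right
globus_pallidus,basal_ganglia,left
globus_pallidus,basal_ganglia,right
thalamus,thalamus,left
thalamus,thalamus,right
mesencephalon_crus_cerebri,mesencephalon,left
mesencephalon_crus_cerebri,mesencephalon,right
mesencephalon_tegmentum,mesencephalon,left
mesencephalon_tegmentum,mesencephalon,right
mesencephalon_tectum,mesencephalon,left
mesencephalon_tectum,mesencephalon,right
pons_ventral,pons,left
pons_ventral,pons,right
pons_tegmental,pons,left
pons_tegmental,pons,right
medulla,medulla,left
medulla,medulla,right
cerebellar_peduncle_superior,cerebellar_peduncle,left
cerebellar_peduncle_superior,cerebellar_peduncle,right
cerebellar_peduncle_middle,cerebellar_peduncle,left
cerebellar_peduncle_middle,cerebellar_peduncle,right
cerebellar_peduncle_inferior,cerebellar_peduncle,left
cerebellar_peduncle_inferior,cerebellar_peduncle,right
cerebellar_hemisphere,cerebellum,left
cerebellar_hemisphere,cerebellum,right
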