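archetype_id,expected
openEHR-EHR-CLUSTER.macroscopy_colorectal_carcinoma.v1,Yes
openEHR-EHR-CLUSTER.microscopy_breast_carcinoma.v1,No
openEHR-EHR-CLUSTER.microscopy_lung_carcinoma.v1,No
openEHR-EHR-CLUSTER.microscopy_lymphoma.v1,Yes
openEHR-EHR-CLUSTER.microscopy_melanoma.v1,No
openEHR-EHR-CLUSTER.microscopy_prostate_carcinoma.v1,No
openEHR-EHR-CLUSTER.tnm_staging-lung_cancer.v1,Yes
openEHR-EHR-EVALUATION.adverse.v1,Yes
openEHR-EHR-EVALUATION.clinical_synopsis.v1,Yes
openEHR-EHR-OBSERVATION.apgar.v1,Yes
openEHR-EHR-OBSERVATION.blood_pressure.v1,No
openEHR-EHR-OBSERVATION.body_mass_index.v1,Yes
openEHR-EHR-OBSERVATION.body_temperature.v1,No
openEHR-EHR-OBSERVATION.body_weight.v1,No
openEHR-EHR-OBSERVATION.height.v1,No
openEHR-EHR-OBSERVATION.respiration.v1,No
openEHR-EHR-CLUSTER.ambient_oxygen.v1,Yes
openEHR-EHR-CLUSTER.anatomical_location-precise.v1,Yes
openEHR-EHR-CLUSTER.device.v1,No
openEHR-EHR-CLUSTER.environmental_conditions.v1,Yes
openEHR-EHR-CLUSTER.level_of_exertion.v1,Yes
openEHR-EHR-CLUSTER.lymph_node_metastases.v1,Yes
openEHR-EHR-CLUSTER.physical_properties.v1,Yes
openEHR-EHR-CLUSTER.tumour_invasion.v1,No
openEHR-EHR-CLUSTER.tumour_resection_margins.v1,No
openEHR-EHR-ELEMENT.last_normal_menstrual_period.v1,Yes
openEHR-EHR-ELEMENT.menstrual_cycle_day.v1,Yes
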