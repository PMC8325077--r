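doctor
doctors
oncologist
oncologists
oncology
nurse
nurses
cancer
treatment
treatments
chemo
chemotherapy
radiation
surgery
appointment
appointments
telehealth
visit
visits
clinic
hospital
care
health
healthcare
medication
medications
prescription
symptoms
pain
scan
scans
screening
survivor
insurance
family
caregiver
therapy
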