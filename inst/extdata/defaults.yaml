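epidemiology:
  n_year1: 161657.0
  annual_growth: 0.2
  horizon_years: 7
  hospital_cohort: 649.0
  parasa:
    total: 2696
    dysplastic: 905
    lg: 751
    hg: 106
    eac: 48
accuracy:
  per_patient_sens: 0.942
  per_patient_spec: 0.944
  per_lesion_sens_nbi: 0.89
  per_lesion_spec_nbi: 0.8
  per_lesion_sens_wle: 0.791
  per_lesion_spec_wle: 0.81
  hist_sens: 1.0
  hist_spec: 0.629
  hist_layer_enabled: no
  lesions_per_patient: 1.0
procedure:
  biopsies_nbi: 3.6
  biopsies_wle: 7.6
  endo_ae_nbi:
    stricture: 0.0001
    perforation: 0.014
    bleeding: 0.002
  endo_ae_wle:
    stricture: 0.0001
    perforation: 0.03
    bleeding: 0.005
  treat_ae:
    stricture: 0.335
    perforation: 0.013
    bleeding: 0.075
  eradication_rate: 0.949
  ae_exposure_basis: per_procedure
economics:
  discount_rate: 0.035
  perspective: NHS
  market_share_nbi: 0.84
  accuracy_level: per_patient
  long_term: no
costs:
  tariff_endoscopy: 517.0
  tariff_emr_rfa: 2101.0
  cost_per_biopsy: 82.0
  ae_costs:
    stricture: 392.0
    bleeding: 392.0
    perforation: 2852.0
  cancer_cost_per_year: 7647.0
  staff_rates:
    admin: 23.0
    nurse_noncontact: 41.0
    consultant_ba: 142.0
    nurse_contact: 100.0
    consultant_during: 142.0
  staff_times_nbi:
    admin: 0.3
    nurse_noncontact: 0.42
    consultant_ba: 0.5
    nurse_contact: 0.3
    consultant_during: 0.3
  staff_times_wle:
    admin: 0.3
    nurse_noncontact: 0.89
    consultant_ba: 0.5
    nurse_contact: 0.3
    consultant_during: 0.3
  consumables:
    snare_pack: 240.0
    snare_pack_units: 20.0
    forceps_pack: 210.0
    forceps_pack_units: 10.0
equipment:
  hospitals: 249.0
  rooms_per_hospital: 3.25
  endoscopists_per_hospital: 3.25
  scopes_per_room: 4.0
  olympus_share: 0.84
  nbi_capable_share: 0.83
  hd_scope_share: 0.4
  trained_share: 0.5
  replacement_rate: 0.029
  unit_cost_system: 41316.0
  unit_cost_scope: 30487.0
  training_cost_per_day_nbi: 1136.0
  training_cost_per_day_wle: 795.0
  training_days_nbi: 2.0
  training_days_wle: 0.0
  maintenance_system_nbi: 4590.0
  maintenance_system_wle: 4527.0
  maintenance_scope_nbi: 4285.0
  maintenance_scope_wle: 4089.0
  amortization_years: 7.0
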