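# Bundled default assumption set.
#
# Everything here is an editable assumption, not a constant of the model:
# replace the CCR tables with your nationally applicable continuation
# tables, the demography file with your country's WRA / in-union / e0
# projections, and the life-table family with the one assigned to your
# country. The bundled CCR tables, demography and life table are
# synthetic defaults constructed for this package (hence the _synthetic
# filenames); they are structurally valid but describe no real country.
cpr_basis: all-women
median_age_sterilisation: 32
demography:
  file: demography_synthetic.csv
life_table:
  file: life_table_synthetic.csv
  family: UN General
methods:
  - name: iud10
    category: long-acting
    max_duration: 10
    ccr_file: ccr_iud10_synthetic.csv
    cyp_factor: 4.6
  - name: iud5
    category: long-acting
    max_duration: 5
    ccr_file: ccr_iud5_synthetic.csv
    cyp_factor: 3.3
  - name: implant5
    category: long-acting
    max_duration: 5
    ccr_file: ccr_implant5_synthetic.csv
    cyp_factor: 3.8
  - name: implant4
    category: long-acting
    max_duration: 4
    ccr_file: ccr_implant4_synthetic.csv
    cyp_factor: 3.2
  - name: implant3
    category: long-acting
    max_duration: 3
    ccr_file: ccr_implant3_synthetic.csv
    cyp_factor: 2.5
  - name: female_sterilisation
    category: permanent
    cyp_factor: 10
  - name: male_sterilisation
    category: permanent
    cyp_factor: 10
  - name: pill
    category: short-term
    units_per_year: 13
    cyp_factor: 0.06666666666666667
  - name: injectable
    category: short-term
    units_per_year: 4
    cyp_factor: 0.25
  - name: condom
    category: short-term
    units_per_year: 120
    cyp_factor: 0.008333333333333333
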