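# Curated CYP2C19 dose-guidance knowledge base.
# Every record is a printed output of the cited primary study; this file is
# a lookup table, not a pharmacokinetic model. Percent adjustments are kept
# as intervals exactly as published.
voriconazole:
  takahashi-2021:
    units: mg/kg
    citation: >-
      Takahashi et al. 2021, CYP2C19 phenotype and body weight-guided
      voriconazole initial dose in infants and children after hematopoietic
      cell transplantation
    target_trough_mg_per_L: [1.5, 5.0]
    nm_weight_bands:
      - {upper_kg: 15, dose: 16}
      - {lower_kg: 15, upper_kg: 30, dose: 12}
      - {lower_kg: 30, dose: 10}
    pm_im_multiplier: [0.50, 0.67]   # doses 33-50% lower
    rm_um_multiplier: [1.25, 1.50]   # doses 25-50% higher
  tian-2021:
    units: mg/kg twice daily
    citation: >-
      Tian et al. 2021, impact of CYP2C19 phenotype and drug-drug
      interactions on voriconazole concentration in pediatric patients
    um_em: {under_12y: 6.53, over_12y: 3.95}
    pm_im: {under_12y: 5.75, over_12y: 4.23}
  chen-2022:
    units: mg/kg/day
    citation: >-
      Chen et al. 2022, combined effect of CYP2C19 genetic polymorphisms and
      C-reactive protein on voriconazole exposure and dosing in
      immunocompromised children
    nm: {median: 20.8, range: [16.2, 26.8]}
    im: {median: 18.2, range: [13.3, 21.8]}
    pm: {median: 15.2, range: [10.7, 19.1]}
  package-insert:
    units: mg/kg per 12 h
    citation: voriconazole package insert, pediatric dosing
    under_2y:
      dose: [5, 7]
      qualifier: suggested adequate range for children under 2 years
    age_2_to_12y:
      dose: 9
      qualifier: IV or oral maintenance, children aged 2-12 years
    over_12y:
      dose: 6
      qualifier: IV loading dose per 12 h, patients older than 12 years
  hicks-2020:
    units: mg twice daily
    citation: >-
      Hicks et al. 2020, prospective CYP2C19-guided voriconazole prophylaxis
      in patients with neutropenic acute myeloid leukemia
    rapid: 300
    ultra-rapid: avoid
    standard: 200
ssri:
  strawn-2019:
    units: mg/day
    citation: >-
      Strawn et al. 2019, CYP2C19-guided escitalopram and sertraline dosing
      in pediatric patients, a pharmacokinetic modeling study
    escitalopram: {poor: 10, normal: 20, ultra-rapid: 30}
    escitalopram_um_note: >-
      twice-daily dosing required in ultra-rapid metabolizers to match
      normal-metabolizer exposure
    sertraline: {poor: 100, normal: 150, rapid: 200, ultra-rapid: 200}
trough_windows:
  default:
    lower: 1.5
    upper: 5.0
    citation: >-
      voriconazole target trough 1.5-5.0 mg/L; >5 mg/L associated with
      adverse effects, <1.5 mg/L with treatment failure
  garcia-garcia:
    lower: 1.0
    upper: 5.5
    citation: >-
      Garcia-Garcia et al. 2021, target concentrations 1-5.5 mg/L measured
      by immunoassay
risk_flags:
  ppi-star17-carrier:
    flag: >-
      CYP2C19*17 carrier: increased PPI inactivation; associated with longer
      acid exposure in refractory GERD and with PPI-insensitive eosinophilic
      esophagitis
    citation: Franciosi et al. 2018; Mougey et al. 2019
  clopidogrel-reduced-activation:
    flag: >-
      reduced formation of the active clopidogrel metabolite in poor and
      intermediate CYP2C19 metabolizers; recommendation extrapolated from
      adult data (no pediatric pharmacogenetic studies available)
    citation: Lee et al. 2022 (CPIC clopidogrel guideline)
  ssri-poor-metabolizer:
    flag: >-
      poor CYP2C19 metabolizers show higher SSRI exposure and more adverse
      effects (including serotonin syndrome and faster weight gain) on
      escitalopram/citalopram
    citation: Aldrich et al. 2019
comedication:
  omeprazole:
    effect: raises
    flag: >-
      omeprazole raises voriconazole trough concentration by competitive
      CYP2C19 inhibition
    citation: Tian et al. 2021
  rifampicin:
    effect: lowers
    flag: >-
      rifampicin lowers voriconazole trough concentration by enzyme
      induction; troughs can stay low for up to 14 days after rifamycin
      discontinuation
    citation: Tian et al. 2021
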