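# Default epidemiological parameters for the salt -> SBP -> CVD mortality
# pathway. Slopes are linear in g/day of salt; relative risks are per
# 20 mmHg higher usual systolic blood pressure, log-linear in SBP.
# Transcribed once from the published meta-analytic literature; each entry
# names its source. Age ranges are matched by band midpoint with
# nearest-range fallback.
version: 1
beta:
  - age_range: "19-30"
    slope_mmhg_per_g_salt: 0.55
    se: 0.15
    provenance: "Salt/BP dose-response, pooled trials and within-population analyses (Law, Frost & Wald 1991, BMJ 302:811), young-adult stratum"
  - age_range: "31-50"
    slope_mmhg_per_g_salt: 0.80
    se: 0.20
    provenance: "Salt/BP dose-response (Law, Frost & Wald 1991, BMJ 302:811), consistent with modest-reduction trial meta-analyses (He, Li & MacGregor 2013, BMJ 346:f1325)"
  - age_range: "51-70"
    slope_mmhg_per_g_salt: 1.05
    se: 0.26
    provenance: "Salt/BP dose-response (Law, Frost & Wald 1991, BMJ 302:811), age-increasing response"
  - age_range: "71+"
    slope_mmhg_per_g_salt: 1.25
    se: 0.31
    provenance: "Salt/BP dose-response (Law, Frost & Wald 1991, BMJ 302:811), oldest stratum"
rr20:
  # Ischaemic heart disease: prospective cohort meta-analysis hazard ratios
  # per 20 mmHg usual SBP (Lewington et al. 2002, Lancet 360:1903),
  # age-at-risk decades.
  - {cause: "I20-25", age_range: "20-49", rr: 2.27, ci_lower: 2.02, ci_upper: 2.56, provenance: "Prospective Studies Collaboration 2002, IHD mortality, ages 40-49 applied to younger adults"}
  - {cause: "I20-25", age_range: "50-59", rr: 1.99, ci_lower: 1.82, ci_upper: 2.17, provenance: "Prospective Studies Collaboration 2002, IHD mortality 50-59"}
  - {cause: "I20-25", age_range: "60-69", rr: 1.84, ci_lower: 1.71, ci_upper: 1.98, provenance: "Prospective Studies Collaboration 2002, IHD mortality 60-69"}
  - {cause: "I20-25", age_range: "70-79", rr: 1.66, ci_lower: 1.56, ci_upper: 1.77, provenance: "Prospective Studies Collaboration 2002, IHD mortality 70-79"}
  - {cause: "I20-25", age_range: "80+", rr: 1.47, ci_lower: 1.36, ci_upper: 1.59, provenance: "Prospective Studies Collaboration 2002, IHD mortality 80-89"}
  # Stroke
  - {cause: "I60-69", age_range: "20-49", rr: 2.78, ci_lower: 2.33, ci_upper: 3.30, provenance: "Prospective Studies Collaboration 2002, stroke mortality, ages 40-49 applied to younger adults"}
  - {cause: "I60-69", age_range: "50-59", rr: 2.63, ci_lower: 2.33, ci_upper: 2.96, provenance: "Prospective Studies Collaboration 2002, stroke mortality 50-59"}
  - {cause: "I60-69", age_range: "60-69", rr: 2.33, ci_lower: 2.13, ci_upper: 2.55, provenance: "Prospective Studies Collaboration 2002, stroke mortality 60-69"}
  - {cause: "I60-69", age_range: "70-79", rr: 2.00, ci_lower: 1.85, ci_upper: 2.16, provenance: "Prospective Studies Collaboration 2002, stroke mortality 70-79"}
  - {cause: "I60-69", age_range: "80+", rr: 1.54, ci_lower: 1.41, ci_upper: 1.68, provenance: "Prospective Studies Collaboration 2002, stroke mortality 80-89"}
  # Heart failure: cohort evidence on usual SBP and incident/fatal heart
  # failure, rescaled to per-20-mmHg.
  - {cause: "I50", age_range: "20-49", rr: 1.90, ci_lower: 1.55, ci_upper: 2.33, provenance: "Cohort meta-analyses of SBP and heart failure, younger adults"}
  - {cause: "I50", age_range: "50-59", rr: 1.80, ci_lower: 1.52, ci_upper: 2.13, provenance: "Cohort meta-analyses of SBP and heart failure 50-59"}
  - {cause: "I50", age_range: "60-69", rr: 1.70, ci_lower: 1.47, ci_upper: 1.96, provenance: "Cohort meta-analyses of SBP and heart failure 60-69"}
  - {cause: "I50", age_range: "70-79", rr: 1.55, ci_lower: 1.37, ci_upper: 1.76, provenance: "Cohort meta-analyses of SBP and heart failure 70-79"}
  - {cause: "I50", age_range: "80+", rr: 1.40, ci_lower: 1.24, ci_upper: 1.58, provenance: "Cohort meta-analyses of SBP and heart failure 80+"}
  # Aortic aneurysm
  - {cause: "I71", age_range: "20-49", rr: 1.85, ci_lower: 1.47, ci_upper: 2.33, provenance: "Prospective Studies Collaboration 2002, other vascular mortality, younger adults"}
  - {cause: "I71", age_range: "50-59", rr: 1.75, ci_lower: 1.44, ci_upper: 2.13, provenance: "Prospective Studies Collaboration 2002, other vascular mortality 50-59"}
  - {cause: "I71", age_range: "60-69", rr: 1.66, ci_lower: 1.41, ci_upper: 1.96, provenance: "Prospective Studies Collaboration 2002, other vascular mortality 60-69"}
  - {cause: "I71", age_range: "70-79", rr: 1.55, ci_lower: 1.34, ci_upper: 1.79, provenance: "Prospective Studies Collaboration 2002, other vascular mortality 70-79"}
  - {cause: "I71", age_range: "80+", rr: 1.45, ci_lower: 1.26, ci_upper: 1.67, provenance: "Prospective Studies Collaboration 2002, other vascular mortality 80+"}
  # Pulmonary embolism: weak BP association; conservative per-20-mmHg RR.
  - {cause: "I26", age_range: "20-49", rr: 1.40, ci_lower: 1.13, ci_upper: 1.73, provenance: "Cohort evidence on BP and venous thromboembolic mortality, younger adults"}
  - {cause: "I26", age_range: "50-59", rr: 1.35, ci_lower: 1.12, ci_upper: 1.63, provenance: "Cohort evidence on BP and venous thromboembolic mortality 50-59"}
  - {cause: "I26", age_range: "60-69", rr: 1.30, ci_lower: 1.11, ci_upper: 1.52, provenance: "Cohort evidence on BP and venous thromboembolic mortality 60-69"}
  - {cause: "I26", age_range: "70-79", rr: 1.25, ci_lower: 1.08, ci_upper: 1.44, provenance: "Cohort evidence on BP and venous thromboembolic mortality 70-79"}
  - {cause: "I26", age_range: "80+", rr: 1.20, ci_lower: 1.05, ci_upper: 1.37, provenance: "Cohort evidence on BP and venous thromboembolic mortality 80+"}
  # Rheumatic heart disease: weak, indirect BP association.
  - {cause: "I05-09", age_range: "20-49", rr: 1.40, ci_lower: 1.10, ci_upper: 1.78, provenance: "Generic BP/CVD mortality association applied to rheumatic heart disease, younger adults"}
  - {cause: "I05-09", age_range: "50-59", rr: 1.35, ci_lower: 1.09, ci_upper: 1.67, provenance: "Generic BP/CVD mortality association applied to rheumatic heart disease 50-59"}
  - {cause: "I05-09", age_range: "60-69", rr: 1.30, ci_lower: 1.08, ci_upper: 1.56, provenance: "Generic BP/CVD mortality association applied to rheumatic heart disease 60-69"}
  - {cause: "I05-09", age_range: "70-79", rr: 1.25, ci_lower: 1.06, ci_upper: 1.47, provenance: "Generic BP/CVD mortality association applied to rheumatic heart disease 70-79"}
  - {cause: "I05-09", age_range: "80+", rr: 1.20, ci_lower: 1.04, ci_upper: 1.39, provenance: "Generic BP/CVD mortality association applied to rheumatic heart disease 80+"}
  # Hypertensive disease: deaths coded to hypertension itself; strongest
  # per-20-mmHg gradient.
  - {cause: "I10-15", age_range: "20-49", rr: 3.20, ci_lower: 2.38, ci_upper: 4.30, provenance: "Cohort evidence on SBP and hypertensive disease mortality, younger adults"}
  - {cause: "I10-15", age_range: "50-59", rr: 2.90, ci_lower: 2.28, ci_upper: 3.69, provenance: "Cohort evidence on SBP and hypertensive disease mortality 50-59"}
  - {cause: "I10-15", age_range: "60-69", rr: 2.60, ci_lower: 2.13, ci_upper: 3.17, provenance: "Cohort evidence on SBP and hypertensive disease mortality 60-69"}
  - {cause: "I10-15", age_range: "70-79", rr: 2.35, ci_lower: 1.98, ci_upper: 2.79, provenance: "Cohort evidence on SBP and hypertensive disease mortality 70-79"}
  - {cause: "I10-15", age_range: "80+", rr: 2.10, ci_lower: 1.80, ci_upper: 2.45, provenance: "Cohort evidence on SBP and hypertensive disease mortality 80+"}
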