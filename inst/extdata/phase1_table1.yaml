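# Phase-1 single-fraction boost constraint set.
# Mandatory rows audit dose to the restricted-diffusion nucleus (c40), the
# boost target volume (btv) and the fall-off shell (eval); conformality
# rows use the stereotactic spillage/gradient indices. Secondary rows are
# optimized but not strict: r50 and ntt_2cm limits are interpolated from
# the PTV-volume-dependent protocol reference table.
# Limits flagged relative_to_px are percentages of the boost prescription.
constraints:
  - {structure: c40, metric: "D100%", kind: dose_pct, pct: 100,
     direction: ">", limit: 100, relative_to_px: true, tier: mandatory}
  - {structure: c40, metric: "D0.03cc", kind: dose_cc, cc: 0.03,
     direction: "<", limit: 125, variation: 130, relative_to_px: true,
     tier: mandatory}
  - {structure: c40, metric: "Dmean", kind: dmean,
     direction: ">", limit: 100, relative_to_px: true, tier: mandatory}
  - {structure: btv, metric: "D95%", kind: dose_pct, pct: 95,
     direction: ">", limit: 100, relative_to_px: true, tier: mandatory}
  - {structure: btv, metric: "D99%", kind: dose_pct, pct: 99,
     direction: ">", limit: 90, relative_to_px: true, tier: mandatory}
  - {structure: btv, metric: "Dmax", kind: dmax,
     direction: "<", limit: 120, variation: 125, relative_to_px: true,
     tier: mandatory}
  - {structure: btv, metric: "Dmean", kind: dmean,
     direction: ">", limit: 100, relative_to_px: true, tier: mandatory}
  - {structure: eval, metric: "V110%px", kind: vol_at_rel_dose,
     level_pct_px: 110, mode: pct, direction: "<", limit: 1,
     tier: mandatory}
  - {structure: plan, metric: "PDS", kind: conformality, key: pds,
     direction: "<", limit: 1.10, variation: 1.15, tier: mandatory}
  - {structure: plan, metric: "MGI", kind: conformality, key: mgi,
     direction: "<", limit: 4.5, variation: 5, tier: mandatory}
  - {structure: plan, metric: "R50", kind: conformality, key: r50,
     direction: "<", limit: reference, reference: r50, tier: secondary}
  - {structure: plan, metric: "NTT_2cm", kind: conformality,
     key: ntt_2cm_pct, direction: "<", limit: reference,
     reference: ntt_2cm, tier: secondary}
  - {structure: plan, metric: "NTT", kind: conformality, key: ntt_px_cc,
     direction: "<", limit: 1, tier: secondary}
  - {structure: bladder, metric: "Dmean", kind: dmean,
     direction: "<", limit: 35, relative_to_px: true, tier: secondary}
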