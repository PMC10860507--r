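# Combined (boost + long-course) plan constraint set for the summed
# physical dose. OAR limits follow standard long-course practice. An OAR
# value beyond its limit by at most variation_fraction of the limit is a
# minor violation, beyond that a major one (documented default, override
# per row with an explicit variation). PTV rows are reported without a
# violation status; their values follow the deviation-from-prescription
# convention (pct_of_px for D98%/excess over prescription for D2%).
variation_fraction: 0.10
constraints:
  - {structure: ptv4500, metric: "D98%", kind: dose_pct, pct: 98,
     report: pct_of_phase_px, phase_px: 45, report_only: true, phase2_only: true}
  - {structure: ptv4500, metric: "D2%", kind: dose_pct, pct: 2,
     report: excess_pct_of_phase_px, phase_px: 45, report_only: true, phase2_only: true}
  - {structure: ptv4500, metric: "Dmean", kind: dmean, report_only: true,
     phase2_only: true}
  - {structure: ptv5000, metric: "D98%", kind: dose_pct, pct: 98,
     report: pct_of_phase_px, phase_px: 50, report_only: true, phase2_only: true}
  - {structure: ptv5000, metric: "D2%", kind: dose_pct, pct: 2,
     report: excess_pct_of_phase_px, phase_px: 50, report_only: true, phase2_only: true}
  - {structure: ptv5000, metric: "Dmean", kind: dmean, report_only: true,
     phase2_only: true}
  - {structure: bladder, metric: "V40Gy", kind: vol_at_dose, level_Gy: 40,
     mode: pct, direction: "<", limit: 40}
  - {structure: bladder, metric: "V45Gy", kind: vol_at_dose, level_Gy: 45,
     mode: pct, direction: "<", limit: 15}
  - {structure: bladder, metric: "Dmax", kind: dmax,
     direction: "<", limit: 50}
  - {structure: bowel_cavity, metric: "V45Gy", kind: vol_at_dose,
     level_Gy: 45, mode: cc, direction: "<", limit: 195}
  - {structure: bowel_cavity, metric: "D1cc", kind: dose_cc, cc: 1,
     report_only: true}
  - {structure: large_bowel, metric: "V30Gy", kind: vol_at_dose,
     level_Gy: 30, mode: cc, direction: "<", limit: 200}
  - {structure: large_bowel, metric: "V35Gy", kind: vol_at_dose,
     level_Gy: 35, mode: cc, direction: "<", limit: 150}
  - {structure: large_bowel, metric: "V45Gy", kind: vol_at_dose,
     level_Gy: 45, mode: cc, direction: "<", limit: 20}
  - {structure: small_bowel, metric: "V15Gy", kind: vol_at_dose,
     level_Gy: 15, mode: cc, direction: "<", limit: 120}
  - {structure: small_bowel, metric: "D1cc", kind: dose_cc, cc: 1,
     direction: "<", limit: 50}
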