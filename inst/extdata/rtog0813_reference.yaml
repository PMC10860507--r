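# PTV-volume-dependent reference limits used for the secondary boost-plan
# conformality constraints, as tabulated in the RTOG 0813 protocol.
# r50: ratio of the 50% prescription isodose volume to the PTV volume.
# ntt_2cm: maximum dose 2 cm from the PTV in any direction, % of prescription.
# Columns: none = no-deviation limit, minor = minor-deviation limit.
# Values outside the tabulated PTV range are linearly extrapolated.
r50:
  rows:
    - {ptv_cc: 1.8,   none: 5.9, minor: 7.5}
    - {ptv_cc: 3.8,   none: 5.5, minor: 6.5}
    - {ptv_cc: 7.4,   none: 5.1, minor: 6.0}
    - {ptv_cc: 13.2,  none: 4.7, minor: 5.8}
    - {ptv_cc: 22.0,  none: 4.5, minor: 5.5}
    - {ptv_cc: 34.0,  none: 4.3, minor: 5.3}
    - {ptv_cc: 50.0,  none: 4.0, minor: 5.0}
    - {ptv_cc: 70.0,  none: 3.5, minor: 4.8}
    - {ptv_cc: 95.0,  none: 3.3, minor: 4.4}
    - {ptv_cc: 126.0, none: 3.1, minor: 4.0}
    - {ptv_cc: 163.0, none: 2.9, minor: 3.7}
ntt_2cm:
  rows:
    - {ptv_cc: 1.8,   none: 50.0, minor: 57.0}
    - {ptv_cc: 3.8,   none: 50.0, minor: 57.0}
    - {ptv_cc: 7.4,   none: 50.0, minor: 58.0}
    - {ptv_cc: 13.2,  none: 50.0, minor: 58.0}
    - {ptv_cc: 22.0,  none: 54.0, minor: 63.0}
    - {ptv_cc: 34.0,  none: 58.0, minor: 68.0}
    - {ptv_cc: 50.0,  none: 62.0, minor: 77.0}
    - {ptv_cc: 70.0,  none: 66.0, minor: 86.0}
    - {ptv_cc: 95.0,  none: 70.0, minor: 89.0}
    - {ptv_cc: 126.0, none: 73.0, minor: 91.0}
    - {ptv_cc: 163.0, none: 77.0, minor: 94.0}
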