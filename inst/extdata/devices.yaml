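# TAVI device catalogue for the radial-equilibrium deployment model.
# Units: mm for diameters/lengths, MPa for pressures.
# nominal_diameter: labelled inflow diameter. frame_length: nominal frame
# height. Self-expanding frames (CV, ER/EPRO) are force-controlled with a
# linear radial pressure curve from peak_pressure at the crimped diameter to
# zero at the nominal diameter; Lotus (LT) is displacement-controlled.
devices:
  - {device_id: "CV 26",      family: "CV",      nominal_diameter: 26, frame_length: 55, mode: force,        peak_pressure: 2.0, crimped_diameter: 6}
  - {device_id: "CV 29",      family: "CV",      nominal_diameter: 29, frame_length: 53, mode: force,        peak_pressure: 2.0, crimped_diameter: 6}
  - {device_id: "CV 31",      family: "CV",      nominal_diameter: 31, frame_length: 52, mode: force,        peak_pressure: 2.0, crimped_diameter: 6}
  - {device_id: "ER/EPRO 26", family: "ER/EPRO", nominal_diameter: 26, frame_length: 45, mode: force,        peak_pressure: 2.2, crimped_diameter: 6}
  - {device_id: "ER/EPRO 29", family: "ER/EPRO", nominal_diameter: 29, frame_length: 45, mode: force,        peak_pressure: 2.2, crimped_diameter: 6}
  - {device_id: "LT 23",      family: "LT",      nominal_diameter: 23, frame_length: 19, mode: displacement, peak_pressure: 0.0, crimped_diameter: 6}
  - {device_id: "LT 25",      family: "LT",      nominal_diameter: 25, frame_length: 19, mode: displacement, peak_pressure: 0.0, crimped_diameter: 6}
  - {device_id: "LT 27",      family: "LT",      nominal_diameter: 27, frame_length: 19, mode: displacement, peak_pressure: 0.0, crimped_diameter: 6}
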