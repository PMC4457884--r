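# Control scenario: healthy red blood cell, single diamide dose.
#
# Units are SI throughout: seconds, metres, molar. Model rate constants and
# collision probabilities live in the packaged rule set (reaction_rules());
# metabolism defaults marked "calibrated" below are calibrated against the
# published time-course shapes, not printed values.

scenario: control       # preset: control | g6pd | reversible_only |
                        #         uniform_dissociation | repeated_dose | spectrin
scale: 1                # membrane sheet area scale; 1 = 2.62 um^2, 4800 dimers
t_end: 7200             # simulated time (s)
seed: 1
record_dt: 10           # time-series cadence (s)

# single 0.25 mM extracellular diamide dose at t = 0 (30% hematocrit
# scaling to the per-cell concentration is applied by the driver)
dose:
  - time_s: 0
    conc_M: 0.25e-3

scheme: bound_site      # cluster dissociation: bound_site | uniform
hemichrome: true        # include irreversible hemichrome reactions 9-15
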