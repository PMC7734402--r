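# Example regression-line config (flat key=value). The coefficients below are
# SYNTHETIC PLACEHOLDERS, not published values: transcribe the slope and
# intercept of the cited regression lines from their original sources before
# using this file for real residual scoring.
#   <metric>.slope=..., <metric>.intercept=..., optional <metric>.orientation=
ivywrel.slope=0.001
ivywrel.intercept=0.35
cvp_bias.slope=0.3
cvp_bias.intercept=-10
gc_16s.slope=0.0012
gc_16s.intercept=0.50
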