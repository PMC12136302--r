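# Example configuration: gabazine condition expressed as a partial
# override of the frozen reference configuration. Omitted keys are
# filled from reference_config(); unknown keys are rejected.
c_ei: 11
c_ii: 11
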