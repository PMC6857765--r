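# Published headline causal estimates (SD of birth weight per SD of
# maternal lipid exposure) from the source study's abstract and results,
# used as *inputs* to reporting transforms (gram conversion). These are not
# outputs of this package.
exposure	method	snp_set	estimate	ci_low	ci_high
hdl	ivw	unrestricted	-0.005	-0.039	0.029
ldl	ivw	unrestricted	0.014	-0.017	0.045
tg	ivw	unrestricted	0.014	-0.025	0.052
ldl	weighted_median	restricted	0.109	0.020	0.198
ldl	weighted_mode	restricted	0.118	0.013	0.222
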