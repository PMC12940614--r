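PredictTLS	17-gene TLS signature selected at log-odds cutoff 0.145	CCL8	CXCL9	CXCL10	CXCL11	CXCR3	CCR3	CCR5	ICAM1	CXCL13	CD40	CD38	DERL3	SSR4	PDCD1	TIGIT	CD274	PIM2
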