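term	estimate
(Intercept)	35.3478228556591
fickett	-18.8452261402975
log_orf	-84.2037508259096
orf_cov	260.553438055393
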