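outcome,exposure,confounders,self,model,true_exposure_effect_zero,outcome_exposure_independent,dichotomized_latent,verdict
0,0,0,0,linear,0,0,0,unbiased
1,0,0,0,linear,0,0,0,biased
0,1,0,0,linear,0,0,0,unbiased
1,1,0,0,linear,0,0,0,biased
0,0,1,0,linear,0,0,0,unbiased
1,0,1,0,linear,0,0,0,biased
0,1,1,0,linear,0,0,0,unbiased
1,1,1,0,linear,0,0,0,biased
0,0,0,1,linear,0,0,0,unbiased
1,0,0,1,linear,0,0,0,biased
0,1,0,1,linear,0,0,0,unbiased
1,1,0,1,linear,0,0,0,biased
0,0,1,1,linear,0,0,0,unbiased
1,0,1,1,linear,0,0,0,biased
0,1,1,1,linear,0,0,0,unbiased
1,1,1,1,linear,0,0,0,biased
0,0,0,0,logistic,0,0,0,unbiased
1,0,0,0,logistic,0,0,0,unbiased
0,1,0,0,logistic,0,0,0,unbiased
1,1,0,0,logistic,0,0,0,biased
0,0,1,0,logistic,0,0,0,unbiased
1,0,1,0,logistic,0,0,0,unbiased
0,1,1,0,logistic,0,0,0,unbiased
1,1,1,0,logistic,0,0,0,biased
0,0,0,1,logistic,0,0,0,unbiased
1,0,0,1,logistic,0,0,0,biased
0,1,0,1,logistic,0,0,0,unbiased
1,1,0,1,logistic,0,0,0,biased
0,0,1,1,logistic,0,0,0,unbiased
1,0,1,1,logistic,0,0,0,biased
0,1,1,1,logistic,0,0,0,unbiased
1,1,1,1,logistic,0,0,0,biased
0,0,0,0,linear,1,0,0,unbiased
1,0,0,0,linear,1,0,0,unbiased
0,1,0,0,linear,1,0,0,unbiased
1,1,0,0,linear,1,0,0,biased
0,0,1,0,linear,1,0,0,unbiased
1,0,1,0,linear,1,0,0,biased
0,1,1,0,linear,1,0,0,unbiased
1,1,1,0,linear,1,0,0,biased
0,0,0,1,linear,1,0,0,unbiased
1,0,0,1,linear,1,0,0,biased
0,1,0,1,linear,1,0,0,unbiased
1,1,0,1,linear,1,0,0,biased
0,0,1,1,linear,1,0,0,unbiased
1,0,1,1,linear,1,0,0,biased
0,1,1,1,linear,1,0,0,unbiased
1,1,1,1,linear,1,0,0,biased
0,0,0,0,logistic,1,0,0,unbiased
1,0,0,0,logistic,1,0,0,unbiased
0,1,0,0,logistic,1,0,0,unbiased
1,1,0,0,logistic,1,0,0,biased
0,0,1,0,logistic,1,0,0,unbiased
1,0,1,0,logistic,1,0,0,unbiased
0,1,1,0,logistic,1,0,0,unbiased
1,1,1,0,logistic,1,0,0,biased
0,0,0,1,logistic,1,0,0,unbiased
1,0,0,1,logistic,1,0,0,biased
0,1,0,1,logistic,1,0,0,unbiased
1,1,0,1,logistic,1,0,0,biased
0,0,1,1,logistic,1,0,0,unbiased
1,0,1,1,logistic,1,0,0,biased
0,1,1,1,logistic,1,0,0,unbiased
1,1,1,1,logistic,1,0,0,biased
0,0,0,0,linear,0,1,0,unbiased
1,0,0,0,linear,0,1,0,biased
0,1,0,0,linear,0,1,0,unbiased
1,1,0,0,linear,0,1,0,biased
0,0,1,0,linear,0,1,0,unbiased
1,0,1,0,linear,0,1,0,biased
0,1,1,0,linear,0,1,0,unbiased
1,1,1,0,linear,0,1,0,biased
0,0,0,1,linear,0,1,0,unbiased
1,0,0,1,linear,0,1,0,biased
0,1,0,1,linear,0,1,0,unbiased
1,1,0,1,linear,0,1,0,biased
0,0,1,1,linear,0,1,0,unbiased
1,0,1,1,linear,0,1,0,biased
0,1,1,1,linear,0,1,0,unbiased
1,1,1,1,linear,0,1,0,biased
0,0,0,0,logistic,0,1,0,unbiased
1,0,0,0,logistic,0,1,0,unbiased
0,1,0,0,logistic,0,1,0,unbiased
1,1,0,0,logistic,0,1,0,unbiased
0,0,1,0,logistic,0,1,0,unbiased
1,0,1,0,logistic,0,1,0,unbiased
0,1,1,0,logistic,0,1,0,unbiased
1,1,1,0,logistic,0,1,0,unbiased
0,0,0,1,logistic,0,1,0,unbiased
1,0,0,1,logistic,0,1,0,unbiased
0,1,0,1,logistic,0,1,0,unbiased
1,1,0,1,logistic,0,1,0,unbiased
0,0,1,1,logistic,0,1,0,unbiased
1,0,1,1,logistic,0,1,0,unbiased
0,1,1,1,logistic,0,1,0,unbiased
1,1,1,1,logistic,0,1,0,unbiased
0,0,0,0,linear,1,1,0,unbiased
1,0,0,0,linear,1,1,0,unbiased
0,1,0,0,linear,1,1,0,unbiased
1,1,0,0,linear,1,1,0,biased
0,0,1,0,linear,1,1,0,unbiased
1,0,1,0,linear,1,1,0,biased
0,1,1,0,linear,1,1,0,unbiased
1,1,1,0,linear,1,1,0,biased
0,0,0,1,linear,1,1,0,unbiased
1,0,0,1,linear,1,1,0,biased
0,1,0,1,linear,1,1,0,unbiased
1,1,0,1,linear,1,1,0,biased
0,0,1,1,linear,1,1,0,unbiased
1,0,1,1,linear,1,1,0,biased
0,1,1,1,linear,1,1,0,unbiased
1,1,1,1,linear,1,1,0,biased
0,0,0,0,logistic,1,1,0,unbiased
1,0,0,0,logistic,1,1,0,unbiased
0,1,0,0,logistic,1,1,0,unbiased
1,1,0,0,logistic,1,1,0,unbiased
0,0,1,0,logistic,1,1,0,unbiased
1,0,1,0,logistic,1,1,0,unbiased
0,1,1,0,logistic,1,1,0,unbiased
1,1,1,0,logistic,1,1,0,unbiased
0,0,0,1,logistic,1,1,0,unbiased
1,0,0,1,logistic,1,1,0,unbiased
0,1,0,1,logistic,1,1,0,unbiased
1,1,0,1,logistic,1,1,0,unbiased
0,0,1,1,logistic,1,1,0,unbiased
1,0,1,1,logistic,1,1,0,unbiased
0,1,1,1,logistic,1,1,0,unbiased
1,1,1,1,logistic,1,1,0,unbiased
0,0,0,0,linear,0,0,1,unbiased
1,0,0,0,linear,0,0,1,biased
0,1,0,0,linear,0,0,1,unbiased
1,1,0,0,linear,0,0,1,biased
0,0,1,0,linear,0,0,1,unbiased
1,0,1,0,linear,0,0,1,biased
0,1,1,0,linear,0,0,1,unbiased
1,1,1,0,linear,0,0,1,biased
0,0,0,1,linear,0,0,1,unbiased
1,0,0,1,linear,0,0,1,biased
0,1,0,1,linear,0,0,1,unbiased
1,1,0,1,linear,0,0,1,biased
0,0,1,1,linear,0,0,1,unbiased
1,0,1,1,linear,0,0,1,biased
0,1,1,1,linear,0,0,1,unbiased
1,1,1,1,linear,0,0,1,biased
0,0,0,0,logistic,0,0,1,unbiased
1,0,0,0,logistic,0,0,1,biased
0,1,0,0,logistic,0,0,1,unbiased
1,1,0,0,logistic,0,0,1,biased
0,0,1,0,logistic,0,0,1,unbiased
1,0,1,0,logistic,0,0,1,biased
0,1,1,0,logistic,0,0,1,unbiased
1,1,1,0,logistic,0,0,1,biased
0,0,0,1,logistic,0,0,1,unbiased
1,0,0,1,logistic,0,0,1,biased
0,1,0,1,logistic,0,0,1,unbiased
1,1,0,1,logistic,0,0,1,biased
0,0,1,1,logistic,0,0,1,unbiased
1,0,1,1,logistic,0,0,1,biased
0,1,1,1,logistic,0,0,1,unbiased
1,1,1,1,logistic,0,0,1,biased
0,0,0,0,linear,1,0,1,unbiased
1,0,0,0,linear,1,0,1,unbiased
0,1,0,0,linear,1,0,1,unbiased
1,1,0,0,linear,1,0,1,biased
0,0,1,0,linear,1,0,1,unbiased
1,0,1,0,linear,1,0,1,biased
0,1,1,0,linear,1,0,1,unbiased
1,1,1,0,linear,1,0,1,biased
0,0,0,1,linear,1,0,1,unbiased
1,0,0,1,linear,1,0,1,biased
0,1,0,1,linear,1,0,1,unbiased
1,1,0,1,linear,1,0,1,biased
0,0,1,1,linear,1,0,1,unbiased
1,0,1,1,linear,1,0,1,biased
0,1,1,1,linear,1,0,1,unbiased
1,1,1,1,linear,1,0,1,biased
0,0,0,0,logistic,1,0,1,unbiased
1,0,0,0,logistic,1,0,1,biased
0,1,0,0,logistic,1,0,1,unbiased
1,1,0,0,logistic,1,0,1,biased
0,0,1,0,logistic,1,0,1,unbiased
1,0,1,0,logistic,1,0,1,biased
0,1,1,0,logistic,1,0,1,unbiased
1,1,1,0,logistic,1,0,1,biased
0,0,0,1,logistic,1,0,1,unbiased
1,0,0,1,logistic,1,0,1,biased
0,1,0,1,logistic,1,0,1,unbiased
1,1,0,1,logistic,1,0,1,biased
0,0,1,1,logistic,1,0,1,unbiased
1,0,1,1,logistic,1,0,1,biased
0,1,1,1,logistic,1,0,1,unbiased
1,1,1,1,logistic,1,0,1,biased
0,0,0,0,linear,0,1,1,unbiased
1,0,0,0,linear,0,1,1,biased
0,1,0,0,linear,0,1,1,unbiased
1,1,0,0,linear,0,1,1,biased
0,0,1,0,linear,0,1,1,unbiased
1,0,1,0,linear,0,1,1,biased
0,1,1,0,linear,0,1,1,unbiased
1,1,1,0,linear,0,1,1,biased
0,0,0,1,linear,0,1,1,unbiased
1,0,0,1,linear,0,1,1,biased
0,1,0,1,linear,0,1,1,unbiased
1,1,0,1,linear,0,1,1,biased
0,0,1,1,linear,0,1,1,unbiased
1,0,1,1,linear,0,1,1,biased
0,1,1,1,linear,0,1,1,unbiased
1,1,1,1,linear,0,1,1,biased
0,0,0,0,logistic,0,1,1,unbiased
1,0,0,0,logistic,0,1,1,biased
0,1,0,0,logistic,0,1,1,unbiased
1,1,0,0,logistic,0,1,1,biased
0,0,1,0,logistic,0,1,1,unbiased
1,0,1,0,logistic,0,1,1,biased
0,1,1,0,logistic,0,1,1,unbiased
1,1,1,0,logistic,0,1,1,biased
0,0,0,1,logistic,0,1,1,unbiased
1,0,0,1,logistic,0,1,1,biased
0,1,0,1,logistic,0,1,1,unbiased
1,1,0,1,logistic,0,1,1,biased
0,0,1,1,logistic,0,1,1,unbiased
1,0,1,1,logistic,0,1,1,biased
0,1,1,1,logistic,0,1,1,unbiased
1,1,1,1,logistic,0,1,1,biased
0,0,0,0,linear,1,1,1,unbiased
1,0,0,0,linear,1,1,1,unbiased
0,1,0,0,linear,1,1,1,unbiased
1,1,0,0,linear,1,1,1,biased
0,0,1,0,linear,1,1,1,unbiased
1,0,1,0,linear,1,1,1,biased
0,1,1,0,linear,1,1,1,unbiased
1,1,1,0,linear,1,1,1,biased
0,0,0,1,linear,1,1,1,unbiased
1,0,0,1,linear,1,1,1,biased
0,1,0,1,linear,1,1,1,unbiased
1,1,0,1,linear,1,1,1,biased
0,0,1,1,linear,1,1,1,unbiased
1,0,1,1,linear,1,1,1,biased
0,1,1,1,linear,1,1,1,unbiased
1,1,1,1,linear,1,1,1,biased
0,0,0,0,logistic,1,1,1,unbiased
1,0,0,0,logistic,1,1,1,biased
0,1,0,0,logistic,1,1,1,unbiased
1,1,0,0,logistic,1,1,1,biased
0,0,1,0,logistic,1,1,1,unbiased
1,0,1,0,logistic,1,1,1,biased
0,1,1,0,logistic,1,1,1,unbiased
1,1,1,0,logistic,1,1,1,biased
0,0,0,1,logistic,1,1,1,unbiased
1,0,0,1,logistic,1,1,1,biased
0,1,0,1,logistic,1,1,1,unbiased
1,1,0,1,logistic,1,1,1,biased
0,0,1,1,logistic,1,1,1,unbiased
1,0,1,1,logistic,1,1,1,biased
0,1,1,1,logistic,1,1,1,unbiased
1,1,1,1,logistic,1,1,1,biased
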