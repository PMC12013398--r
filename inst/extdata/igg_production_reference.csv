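dataset,experimental_flux,model_flux
hp,2.02e-5,2.04e-5
late_exponential,2.44e-5,3.205e-5
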