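subregion,real_rate
Alto Minho,74.10
Ave,72.09
Cávado,67.02
Douro,66.86
Entre Douro e Vouga,66.25
Metropolitan Area of Porto,63.38
Tâmega e Sousa,67.59
Trás-os-Montes,65.69
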