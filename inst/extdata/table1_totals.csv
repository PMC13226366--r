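population,year,total_millions
main,2022,50.5
main,2030,59.9
main,2040,62.1
alternative,2022,62.8
alternative,2030,74.4
alternative,2040,77.2
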