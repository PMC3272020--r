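A01	healthy
A02	healthy
A03	healthy
A04	healthy
A05	healthy
A06	healthy
A07	healthy
A08	healthy
A09	healthy
A10	healthy
A11	healthy
A12	healthy
B01	dysbiotic
B02	dysbiotic
B03	dysbiotic
B04	dysbiotic
B05	dysbiotic
B06	dysbiotic
B07	dysbiotic
B08	dysbiotic
B09	dysbiotic
B10	dysbiotic
B11	dysbiotic
B12	dysbiotic
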