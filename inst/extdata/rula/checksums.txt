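d9359761ba69da21115e71b54c5eb63e table_a.csv
1350844bf3109d4e51007c5843ee17e0 table_b.csv
a7f329be7bd050e126d5aa6d4d1ef19f table_c.csv
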