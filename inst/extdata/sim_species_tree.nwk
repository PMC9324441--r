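((((((((sp01:1,sp02:1):2.8,(sp03:1.4,sp04:1.4):2.4):0.05,sp09:3.85):0.02,(sp05:0.8,sp06:0.8):3.07):0.16,(sp07:1.8,sp08:1.8):2.23):0.3,sp10:4.33):1.17,sp11:5.5):1.5,sp12:7);
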