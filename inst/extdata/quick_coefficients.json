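{"c0":0,"c1":-0.675840811809459,"c2":0.0382841673906368,"c3":1.62724763628538e-05,"surface_cap":1,"buried_cap":4.5}
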