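specimen_id	species	genus	subfamily
a1	Alphaia una	Alphaia	Testinae
a2	Alphaia una	Alphaia	Testinae
b1	Alphaia duo	Alphaia	Testinae
c1	Betaia tria	Betaia	Testinae
c2	Betaia tria	Betaia	Testinae
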