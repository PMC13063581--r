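state,specialists_per_10k
Baden-Wuerttemberg,6.4
Bavaria,5.8
Berlin,10.27
Brandenburg,1.4
Bremen,12.73
Hamburg,10.73
Hesse,7.1
Mecklenburg Western Pomerania,0.4
Lower Saxony,4.2
North Rhine-Westphalia,6.8
Rhineland-Palatinate,3.6
Saarland,4.9
Saxony,2.3
Saxony-Anhalt,1.8
Schleswig-Holstein,1.1
Thuringia,1.6
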