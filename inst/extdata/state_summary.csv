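state,population,n_participants,n_users
Baden-Wuerttemberg,44651,115,72
Bavaria,54061,212,155
Berlin,59394,282,218
Brandenburg,8395,20,12
Bremen,3930,9,8
Hamburg,17713,78,62
Hesse,31422,134,99
Mecklenburg Western Pomerania,6329,19,14
Lower Saxony,28175,79,56
North Rhine-Westphalia,79376,301,198
Rhineland-Palatinate,13156,57,43
Saarland,4520,12,8
Saxony,20499,57,36
Saxony-Anhalt,7454,15,6
Schleswig-Holstein,13395,16,12
Thuringia,6956,12,6
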