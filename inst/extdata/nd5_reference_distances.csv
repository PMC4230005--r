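id,Human,Gorilla,Pi-chim,C-chim,Fin-whale,Blue-whale,Rat,Mouse,Opossum,Sheep,Goat,Lemur,Cattle,Hare,Gallus,Rabbit
Human,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Gorilla,0.1111,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Pi-chim,0.0720,0.0833,0,0,0,0,0,0,0,0,0,0,0,0,0,0
C-chim,0.0814,0.0865,0.0510,0,0,0,0,0,0,0,0,0,0,0,0,0
Fin-whale,0.3396,0.3285,0.3222,0.3301,0,0,0,0,0,0,0,0,0,0,0,0
Blue-whale,0.3474,0.3333,0.3285,0.3301,0.0324,0,0,0,0,0,0,0,0,0,0,0
Rat,0.3693,0.3622,0.3636,0.3716,0.3333,0.3381,0,0,0,0,0,0,0,0,0,0
Mouse,0.3740,0.3686,0.3716,0.3748,0.3317,0.3333,0.1883,0,0,0,0,0,0,0,0,0
Opossum,0.4476,0.4551,0.4290,0.4418,0.4515,0.4519,0.4513,0.4479,0,0,0,0,0,0,0,0
Sheep,0.3020,0.2933,0.2871,0.2951,0.2023,0.2067,0.3149,0.3219,0.4121,0,0,0,0,0,0,0
Goat,0.3036,0.2901,0.2871,0.2919,0.1958,0.2147,0.3166,0.3468,0.4202,0.0712,0,0,0,0,0,0
Lemur,0.2989,0.2708,0.2839,0.2967,0.2557,0.2724,0.3166,0.3670,0.4055,0.2087,0.2317,0,0,0,0,0
Cattle,0.3114,0.3045,0.3046,0.3062,0.1958,0.2051,0.3149,0.3173,0.4235,0.0906,0.1254,0.2184,0,0,0,0
Hare,0.3146,0.3157,0.3062,0.3046,0.2832,0.2788,0.3166,0.3421,0.4023,0.2217,0.2508,0.2053,0.2532,0,0,0
Gallus,0.4726,0.4920,0.4737,0.5008,0.4450,0.4423,0.4903,0.4743,0.4691,0.4239,0.4524,0.4680,0.4183,0.4660,0,0
Rabbit,0.3255,0.3189,0.3222,0.3142,0.2896,0.2756,0.3084,0.3390,0.4332,0.2184,0.2603,0.2282,0.2612,0.0837,0.4434,0
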