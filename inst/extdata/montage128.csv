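label,x,y,cluster
E1,0,0,
E2,0,0.15,
E3,0.129904,0.075,
E4,0.129904,-0.075,
E5,0,-0.15,
E6,-0.129904,-0.075,
E7,-0.129904,0.075,
E8,0,0.3,
E9,0.15,0.259808,
E10,0.259808,0.15,
E11,0.3,0,
E12,0.259808,-0.15,
E13,0.15,-0.259808,
E14,0,-0.3,
E15,-0.15,-0.259808,
E16,-0.259808,-0.15,
E17,-0.3,0,
E18,-0.259808,0.15,
E19,-0.15,0.259808,
E20,0,0.45,
E21,0.153909,0.422862,R
E22,0.289254,0.34472,R
E23,0.389711,0.225,
E24,0.443163,0.078142,
E25,0.443163,-0.078142,
E26,0.389711,-0.225,
E27,0.289254,-0.34472,
E28,0.153909,-0.422862,
E29,0,-0.45,
E30,-0.153909,-0.422862,
E31,-0.289254,-0.34472,
E32,-0.389711,-0.225,
E33,-0.443163,-0.078142,
E34,-0.443163,0.078142,
E35,-0.389711,0.225,
E36,-0.289254,0.34472,L
E37,-0.153909,0.422862,L
E38,0,0.6,
E39,0.155291,0.579555,
E40,0.3,0.519615,R
E41,0.424264,0.424264,R
E42,0.519615,0.3,R
E43,0.579555,0.155291,
E44,0.6,0,
E45,0.579555,-0.155291,
E46,0.519615,-0.3,
E47,0.424264,-0.424264,
E48,0.3,-0.519615,
E49,0.155291,-0.579555,
E50,0,-0.6,
E51,-0.155291,-0.579555,
E52,-0.3,-0.519615,
E53,-0.424264,-0.424264,
E54,-0.519615,-0.3,
E55,-0.579555,-0.155291,
E56,-0.6,0,
E57,-0.579555,0.155291,
E58,-0.519615,0.3,L
E59,-0.424264,0.424264,L
E60,-0.3,0.519615,L
E61,-0.155291,0.579555,
E62,0,0.75,
E63,0.155934,0.733611,
E64,0.305052,0.685159,
E65,0.440839,0.606763,R
E66,0.557359,0.501848,R
E67,0.649519,0.375,
E68,0.713292,0.231763,
E69,0.745891,0.078396,
E70,0.745891,-0.078396,
E71,0.713292,-0.231763,
E72,0.649519,-0.375,
E73,0.557359,-0.501848,
E74,0.440839,-0.606763,
E75,0.305052,-0.685159,
E76,0.155934,-0.733611,
E77,0,-0.75,
E78,-0.155934,-0.733611,
E79,-0.305052,-0.685159,
E80,-0.440839,-0.606763,
E81,-0.557359,-0.501848,
E82,-0.649519,-0.375,
E83,-0.713292,-0.231763,
E84,-0.745891,-0.078396,
E85,-0.745891,0.078396,
E86,-0.713292,0.231763,
E87,-0.649519,0.375,
E88,-0.557359,0.501848,L
E89,-0.440839,0.606763,L
E90,-0.305052,0.685159,
E91,-0.155934,0.733611,
E92,0,0.9,
E93,0.152101,0.887054,
E94,0.299826,0.84859,
E95,0.438925,0.785713,
E96,0.565398,0.700232,
E97,0.675605,0.594607,
E98,0.766376,0.471877,
E99,0.8351,0.335571,
E100,0.8798,0.189611,
E101,0.899189,0.038197,
E102,0.89271,-0.114316,
E103,0.86055,-0.26354,
E104,0.803633,-0.405183,
E105,0.723597,-0.53517,
E106,0.622745,-0.64976,
E107,0.503977,-0.745659,
E108,0.370711,-0.820106,
E109,0.22678,-0.87096,
E110,0.076325,-0.896758,
E111,-0.076325,-0.896758,
E112,-0.22678,-0.87096,
E113,-0.370711,-0.820106,
E114,-0.503977,-0.745659,
E115,-0.622745,-0.64976,
E116,-0.723597,-0.53517,
E117,-0.803633,-0.405183,
E118,-0.86055,-0.26354,
E119,-0.89271,-0.114316,
E120,-0.899189,0.038197,
E121,-0.8798,0.189611,
E122,-0.8351,0.335571,
E123,-0.766376,0.471877,
E124,-0.675605,0.594607,
E125,-0.565398,0.700232,
E126,-0.438925,0.785713,
E127,-0.299826,0.84859,
E128,-0.152101,0.887054,
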