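species,element,mean,sd,n,letter
duck,Li,0.0473,0.0252,30,a
chicken,Li,0.043,0.0191,30,a
bovine,Li,0.0418,0.0312,30,a
pig,Li,0.0357,0.0195,30,a
sheep,Li,0.0426,0.0137,30,a
duck,Be,0.0798,0.1812,30,a
chicken,Be,0.1876,0.3958,30,a
bovine,Be,0.236,0.5341,30,a
pig,Be,0.0946,0.2598,30,a
sheep,Be,0.0892,0.2512,30,a
duck,B,0.275,0.2226,30,ab
chicken,B,0.221,0.163,30,ab
bovine,B,0.537,1.37,30,a
pig,B,0.284,0.301,30,ab
sheep,B,0.203,0.130,30,b
duck,Al,1.62,0.922,30,ab
chicken,Al,2.17,2.98,30,ab
bovine,Al,1.42,1.07,30,b
pig,Al,2.62,1.07,30,a
sheep,Al,2.19,3.18,30,ab
duck,Ti,0.593,0.522,30,a
chicken,Ti,0.593,0.619,30,a
bovine,Ti,0.818,1.25,30,a
pig,Ti,0.579,0.680,30,a
sheep,Ti,0.523,0.469,30,a
duck,V,0.0493,0.0943,30,ab
chicken,V,0.0795,0.166,30,ab
bovine,V,0.142,0.341,30,a
pig,V,0.0483,0.118,30,ab
sheep,V,0.0401,0.116,30,b
duck,Cr,0.154,0.182,30,b
chicken,Cr,0.285,0.163,30,ab
bovine,Cr,0.385,0.412,30,a
pig,Cr,0.283,0.133,30,ab
sheep,Cr,0.244,0.138,30,b
duck,Mn,0.158,0.147,30,ab
chicken,Mn,0.209,0.154,30,a
bovine,Mn,0.119,0.129,30,b
pig,Mn,0.174,0.0712,30,ab
sheep,Mn,0.181,0.0983,30,ab
duck,Fe,809,129,30,c
chicken,Fe,5709,152,30,a
bovine,Fe,728,280,30,c
pig,Fe,948,134,30,b
sheep,Fe,730,117,30,c
duck,Co,0.0200,0.0181,30,a
chicken,Co,0.0153,0.0351,30,a
bovine,Co,0.0164,0.0500,30,a
pig,Co,0.00740,0.0172,30,a
sheep,Co,0.00720,0.0182,30,a
duck,Ni,0.0855,0.104,30,b
chicken,Ni,0.287,0.637,30,a
bovine,Ni,0.157,0.0617,30,ab
pig,Ni,0.179,0.0939,30,ab
sheep,Ni,0.134,0.0412,30,b
duck,Cu,0.597,0.314,30,c
chicken,Cu,0.908,1.74,30,c
bovine,Cu,2.43,0.532,30,a
pig,Cu,1.50,0.164,30,b
sheep,Cu,1.44,0.228,30,b
duck,Zn,6.18,3.96,30,b
chicken,Zn,8.416,8.10,30,b
bovine,Zn,119,440,30,a
pig,Zn,10.4,19.2,30,b
sheep,Zn,3.89,0.725,30,b
duck,As,0.00790,0.00680,30,a
chicken,As,0.00750,0.00600,30,a
bovine,As,0.00990,0.0156,30,a
pig,As,0.00650,0.00430,30,a
sheep,As,0.00590,0.00400,30,a
duck,Se,0.327,0.0670,30,a
chicken,Se,0.244,0.0552,30,c
bovine,Se,0.312,0.0812,30,ab
pig,Se,0.345,0.0795,30,a
sheep,Se,0.286,0.0529,30,b
duck,Rb,0.0530,0.0294,30,ab
chicken,Rb,0.0394,0.0158,30,b
bovine,Rb,0.0505,0.0288,30,ab
pig,Rb,0.0639,0.0413,30,a
sheep,Rb,0.0426,0.0185,30,b
duck,Sr,0.144,0.0725,30,b
chicken,Sr,0.159,0.0767,30,b
bovine,Sr,0.246,0.109,30,a
pig,Sr,0.148,0.0424,30,b
sheep,Sr,0.232,0.0744,30,a
duck,Cd,0.0134,0.0321,30,a
chicken,Cd,0.0349,0.0835,30,a
bovine,Cd,0.0283,0.0905,30,a
pig,Cd,0.00680,0.0248,30,a
sheep,Cd,0.00980,0.0282,30,a
duck,Ba,0.101,0.0423,30,b
chicken,Ba,0.094,0.0641,30,b
bovine,Ba,0.144,0.0948,30,a
pig,Ba,0.0902,0.0355,30,b
sheep,Ba,0.142,0.0543,30,a
duck,Tl,0.0841,0.258,30,a
chicken,Tl,0.300,0.775,30,a
bovine,Tl,0.244,0.685,30,a
pig,Tl,0.0992,0.337,30,a
sheep,Tl,0.104,0.353,30,a
duck,Pb,0.318,0.163,30,a
chicken,Pb,0.391,0.707,30,a
bovine,Pb,0.308,0.527,30,a
pig,Pb,0.243,0.165,30,a
sheep,Pb,0.270,0.229,30,a
duck,Na,1880,401,30,ab
chicken,Na,1764,293,30,ab
bovine,Na,2050,400,30,a
pig,Na,1500,1850,30,b
sheep,Na,1840,517,30,ab
duck,Mg,148,27.7,30,a
chicken,Mg,86.5,13.5,30,b
bovine,Mg,46.7,6.97,30,b
pig,Mg,153,207,30,a
sheep,Mg,50.2,10.7,30,b
duck,Ca,90.1,39.1,30,a
chicken,Ca,101,25.9,30,a
bovine,Ca,96.2,18.1,30,a
pig,Ca,60.3,81.8,30,b
sheep,Ca,59.0,41.1,30,b
duck,K,1760,388,30,b
chicken,K,1730,300,30,b
bovine,K,646,368,30,c
pig,K,2300,2200,30,a
sheep,K,1030,124,30,c
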