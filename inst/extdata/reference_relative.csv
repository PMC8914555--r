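species,element,mean,sd,n,letter
duck,Li,1.02e-05,0.565e-05,30,ab
chicken,Li,1.02e-05,0.449e-05,30,ab
bovine,Li,1.16e-05,0.948e-05,30,a
pig,Li,0.836e-05,0.496e-05,30,b
sheep,Li,1.17e-05,0.404e-05,30,a
duck,Be,1.68e-05,3.65e-05,30,a
chicken,Be,4.47e-05,9.53e-05,30,a
bovine,Be,5.59e-05,11.0e-05,30,a
pig,Be,2.17e-05,6.01e-05,30,a
sheep,Be,2.60e-05,7.42e-05,30,a
duck,B,5.99e-05,5.06e-05,30,a
chicken,B,5.17e-05,3.66e-05,30,a
bovine,B,10.4e-05,19.5e-05,30,a
pig,B,6.63e-05,7.11e-05,30,a
sheep,B,5.54e-05,3.94e-05,30,a
duck,Al,3.54e-04,2.18e-04,30,c
chicken,Al,5.07e-04,7.01e-04,30,abc
bovine,Al,3.89e-04,2.91e-04,30,bc
pig,Al,6.06e-04,2.77e-04,30,ab
sheep,Al,6.15e-04,9.26e-04,30,a
duck,Ti,1.27e-04,1.11e-04,30,a
chicken,Ti,1.39e-04,1.45e-04,30,a
bovine,Ti,2.10e-04,2.98e-04,30,a
pig,Ti,1.33e-04,1.49e-04,30,a
sheep,Ti,1.47e-04,1.39e-04,30,a
duck,V,1.04e-05,1.89e-05,30,b
chicken,V,1.89e-05,4.00e-05,30,ab
bovine,V,3.27e-05,6.31e-05,30,a
pig,V,1.11e-05,2.72e-05,30,b
sheep,V,1.16e-05,3.42e-05,30,b
duck,Cr,3.21e-05,3.64e-05,30,c
chicken,Cr,6.77e-05,4.02e-05,30,b
bovine,Cr,9.91e-05,6.56e-05,30,a
pig,Cr,6.57e-05,3.30e-05,30,b
sheep,Cr,6.83e-05,4.37e-05,30,b
duck,Mn,3.42e-05,3.32e-05,30,b
chicken,Mn,4.96e-05,3.71e-05,30,a
bovine,Mn,3.04e-05,2.39e-05,30,b
pig,Mn,3.93e-05,1.54e-05,30,ab
sheep,Mn,4.97e-05,2.86e-05,30,a
duck,Fe,0.173,0.0252,30,a
chicken,Fe,0.134,0.0337,30,d
bovine,Fe,0.197,0.0460,30,b
pig,Fe,0.221,0.0504,30,a
sheep,Fe,0.198,0.0354,30,b
duck,Co,4.29e-06,3.84e-06,30,a
chicken,Co,3.65e-06,8.51e-06,30,a
bovine,Co,3.21e-06,6.83e-06,30,a
pig,Co,1.70e-06,4.00e-06,30,a
sheep,Co,2.06e-06,5.38e-06,30,a
duck,Ni,1.81e-05,2.18e-05,30,b
chicken,Ni,6.31e-05,12.5e-05,30,a
bovine,Ni,4.38e-05,1.84e-05,30,ab
pig,Ni,4.22e-05,2.53e-05,30,ab
sheep,Ni,3.71e-05,1.44e-05,30,ab
duck,Cu,1.26e-04,5.65e-05,30,c
chicken,Cu,20.2e-05,34.0e-05,30,c
bovine,Cu,68.9e-05,20.4e-05,30,a
pig,Cu,35.2e-05,7.78e-05,30,b
sheep,Cu,39.4e-05,8.80e-05,30,b
duck,Zn,1.36e-03,1.05e-03,30,b
chicken,Zn,1.94e-03,1.78e-03,30,b
bovine,Zn,17.2e-03,60.0e-03,30,a
pig,Zn,2.42e-03,4.45e-03,30,b
sheep,Zn,1.06e-03,0.235e-03,30,b
duck,As,1.69e-06,1.39e-06,30,ab
chicken,As,1.77e-06,1.43e-06,30,ab
bovine,As,2.55e-06,3.67e-06,30,a
pig,As,1.48e-06,1.01e-06,30,b
sheep,As,1.64e-06,1.18e-06,30,ab
duck,Se,7.00e-05,1.40e-05,30,b
chicken,Se,5.79e-05,1.41e-05,30,c
bovine,Se,8.82e-05,2.95e-05,30,a
pig,Se,8.02e-05,2.36e-05,30,ab
sheep,Se,7.84e-05,1.79e-05,30,ab
duck,Rb,1.14e-05,0.618e-05,30,ab
chicken,Rb,0.933e-05,0.385e-05,30,b
bovine,Rb,1.43e-05,0.929e-05,30,a
pig,Rb,1.49e-05,1.08e-05,30,a
sheep,Rb,1.18e-05,0.560e-05,30,ab
duck,Sr,3.13e-05,1.68e-05,30,b
chicken,Sr,3.71e-05,1.75e-05,30,b
bovine,Sr,6.73e-05,2.53e-05,30,a
pig,Sr,3.48e-05,1.24e-05,30,b
sheep,Sr,6.34e-05,2.22e-05,30,a
duck,Cd,3.05e-06,7.45e-06,30,ab
chicken,Cd,8.19e-06,20.0e-06,30,a
bovine,Cd,5.41e-06,12.7e-06,30,ab
pig,Cd,1.55e-06,5.74e-06,30,b
sheep,Cd,2.74e-06,8.20e-06,30,ab
duck,Ba,2.19e-05,0.972e-05,30,b
chicken,Ba,2.21e-05,1.53e-05,30,b
bovine,Ba,3.84e-05,1.84e-05,30,a
pig,Ba,2.09e-05,0.914e-05,30,b
sheep,Ba,3.90e-05,1.62e-05,30,a
duck,Tl,1.74e-05,5.13e-05,30,a
chicken,Tl,7.16e-05,18.8e-05,30,a
bovine,Tl,5.19e-05,12.3e-05,30,a
pig,Tl,2.29e-05,7.79e-05,30,a
sheep,Tl,3.01e-05,10.4e-05,30,a
duck,Pb,6.83e-05,3.48e-05,30,a
chicken,Pb,9.42e-05,17.5e-05,30,a
bovine,Pb,7.30e-05,8.27e-05,30,a
pig,Pb,5.78e-05,4.24e-05,30,a
sheep,Pb,7.54e-05,6.61e-05,30,a
duck,Na,0.401,0.0636,30,c
chicken,Na,0.413,0.0581,30,c
bovine,Na,0.575,0.109,30,a
pig,Na,0.283,0.0875,30,d
sheep,Na,0.486,0.0740,30,b
duck,Mg,0.0316,0.00522,30,a
chicken,Mg,0.0202,0.00220,30,c
bovine,Mg,0.0131,0.00236,30,d
pig,Mg,0.0283,0.00464,30,b
sheep,Mg,0.0139,0.00461,30,d
duck,Ca,0.0191,0.00855,30,c
chicken,Ca,0.0236,0.00512,30,b
bovine,Ca,0.02691,0.00614,30,a
pig,Ca,0.0110,0.00591,30,d
sheep,Ca,0.0160,0.0103,30,c
duck,K,0.373,0.0673,30,c
chicken,K,0.406,0.0426,30,b
bovine,K,0.169,0.0371,30,e
pig,K,0.453,0.0678,30,a
sheep,K,0.283,0.0535,30,d
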