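var,T,pH,Na,K,Ca,Al,Fe,Mg,Cl,NH4,SO4,NO3,P,Si,B,As,Zn,Mn,S2,O2,Genera,EC,Clusters
T,1.00,-0.35,0.16,0.10,-0.26,0.17,0.02,-0.23,0.25,0.16,0.08,0.27,-0.32,0.36,0.22,0.14,0.24,0.12,-0.06,-0.41,-0.59,-0.57,-0.37
pH,-0.35,1.00,0.36,-0.10,-0.02,-0.61,-0.60,-0.05,-0.26,-0.01,-0.26,0.35,0.01,-0.21,-0.02,-0.03,-0.62,-0.33,0.05,0.48,0.71,0.62,0.63
Na,0.16,0.36,1.00,-0.06,-0.45,-0.31,-0.42,-0.49,0.65,-0.35,-0.69,0.47,-0.48,0.65,0.12,0.19,-0.05,-0.43,-0.51,0.18,0.18,0.35,0.50
K,0.10,-0.10,-0.06,1.00,0.30,-0.14,-0.12,0.30,0.28,0.06,0.16,-0.34,0.00,-0.19,0.75,0.55,0.04,-0.14,0.42,-0.26,-0.41,-0.29,-0.36
Ca,-0.26,-0.02,-0.45,0.30,1.00,-0.12,-0.10,0.99,-0.19,-0.09,0.40,-0.29,0.55,-0.64,-0.10,0.00,-0.14,-0.14,0.63,-0.25,0.07,-0.12,-0.16
Al,0.17,-0.61,-0.31,-0.14,-0.12,1.00,0.93,-0.06,-0.21,-0.09,0.26,-0.17,-0.15,0.22,-0.13,-0.16,0.38,0.19,-0.21,-0.15,-0.38,-0.27,-0.37
Fe,0.02,-0.60,-0.42,-0.12,-0.10,0.93,1.00,-0.05,-0.32,-0.08,0.25,-0.27,0.05,0.10,-0.13,-0.16,0.33,0.31,-0.20,-0.17,-0.31,-0.21,-0.33
Mg,-0.23,-0.05,-0.49,0.30,0.99,-0.06,-0.05,1.00,-0.23,-0.02,0.49,-0.27,0.52,-0.65,-0.11,-0.03,-0.13,-0.15,0.68,-0.28,0.05,-0.14,-0.18
Cl,0.25,-0.26,0.65,0.28,-0.19,-0.21,-0.32,-0.23,1.00,-0.29,-0.45,0.01,-0.40,0.65,0.25,0.30,0.40,-0.35,-0.27,-0.08,-0.33,-0.14,-0.03
NH4,0.16,-0.01,-0.35,0.06,-0.09,-0.09,-0.08,-0.02,-0.29,1.00,0.77,0.30,0.07,-0.19,0.30,0.20,-0.13,-0.08,0.57,-0.19,-0.01,-0.03,-0.01
SO4,0.08,-0.26,-0.69,0.16,0.40,0.26,0.25,0.49,-0.45,0.77,1.00,0.02,0.27,-0.44,0.09,-0.01,-0.01,-0.07,0.79,-0.36,-0.12,-0.21,-0.27
NO3,0.27,0.35,0.47,-0.34,-0.29,-0.17,-0.27,-0.27,0.01,0.30,0.02,1.00,-0.21,0.29,-0.10,-0.12,-0.36,-0.33,0.00,-0.01,0.36,0.44,0.50
P,-0.32,0.01,-0.48,0.00,0.55,-0.15,0.05,0.52,-0.40,0.07,0.27,-0.21,1.00,-0.60,-0.18,-0.11,-0.20,0.12,0.41,-0.24,0.23,0.06,0.04
Si,0.36,-0.21,0.65,-0.19,-0.64,0.22,0.10,-0.65,0.65,-0.19,-0.44,0.29,-0.60,1.00,0.12,0.16,0.33,-0.23,-0.59,0.15,-0.20,0.04,0.13
B,0.22,-0.02,0.12,0.75,-0.10,-0.13,-0.13,-0.11,0.25,0.30,0.09,-0.10,-0.18,0.12,1.00,0.89,-0.06,-0.05,0.15,-0.22,-0.39,-0.21,-0.21
As,0.14,-0.03,0.19,0.55,0.00,-0.16,-0.16,-0.03,0.30,0.20,-0.01,-0.12,-0.11,0.16,0.89,1.00,-0.11,-0.06,-0.02,-0.14,-0.28,-0.15,-0.07
Zn,0.24,-0.62,-0.05,0.04,-0.14,0.38,0.33,-0.13,0.40,-0.13,-0.01,-0.36,-0.20,0.33,-0.06,-0.11,1.00,0.07,-0.16,-0.20,-0.54,-0.38,-0.36
Mn,0.12,-0.33,-0.43,-0.14,-0.14,0.19,0.31,-0.15,-0.35,-0.08,-0.07,-0.33,0.12,-0.23,-0.05,-0.06,0.07,1.00,-0.23,-0.16,-0.27,-0.36,-0.34
S2,-0.06,0.05,-0.51,0.42,0.63,-0.21,-0.20,0.68,-0.27,0.57,0.79,0.00,0.41,-0.59,0.15,-0.02,-0.16,-0.23,1.00,-0.35,0.09,-0.04,-0.10
O2,-0.41,0.48,0.18,-0.26,-0.25,-0.15,-0.17,-0.28,-0.08,-0.19,-0.36,-0.01,-0.24,0.15,-0.22,-0.14,-0.20,-0.16,-0.35,1.00,0.46,0.48,0.42
Genera,-0.59,0.71,0.18,-0.41,0.07,-0.38,-0.31,0.05,-0.33,-0.01,-0.12,0.36,0.23,-0.20,-0.39,-0.28,-0.54,-0.27,0.09,0.46,1.00,0.91,0.87
EC,-0.57,0.62,0.35,-0.29,-0.12,-0.27,-0.21,-0.14,-0.14,-0.03,-0.21,0.44,0.06,0.04,-0.21,-0.15,-0.38,-0.36,-0.04,0.48,0.91,1.00,0.92
Clusters,-0.37,0.63,0.50,-0.36,-0.16,-0.37,-0.33,-0.18,-0.03,-0.01,-0.27,0.50,0.04,0.13,-0.21,-0.07,-0.36,-0.34,-0.10,0.42,0.87,0.92,1.00
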