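# synthetic hepatocyte marker panel used by the cohort generator
# replace with a curated liver-specific marker list for real data
HEP.001
HEP.002
HEP.003
HEP.004
HEP.005
HEP.006
HEP.007
HEP.008
HEP.009
HEP.010
HEP.011
HEP.012
HEP.013
HEP.014
HEP.015
HEP.016
HEP.017
HEP.018
HEP.019
HEP.020
HEP.021
HEP.022
HEP.023
HEP.024
HEP.025
HEP.026
HEP.027
HEP.028
HEP.029
HEP.030
HEP.031
HEP.032
HEP.033
HEP.034
HEP.035
HEP.036
HEP.037
HEP.038
HEP.039
HEP.040
HEP.041
HEP.042
HEP.043
HEP.044
HEP.045
HEP.046
HEP.047
HEP.048
HEP.049
HEP.050
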