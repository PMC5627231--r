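# Default model configuration: published calibration of the two-step
# denitrification RSCM and the measured batch initial condition.
# Format: params.<name> = value / init.<name> = value

params.f1 = 0.56
params.f2 = 0.99
params.k1 = 6.23
params.k2 = 5.71
params.Kd1 = 0.25
params.Kd2 = 0.25
params.Ka1 = 0.001
params.Ka2 = 0.004
params.kdeg = 0.11
params.kR1 = 2.84
params.kR2 = 1.03
params.kT1 = 0.13
params.kT2 = 0.25
params.kE1 = 1.84
params.kE2 = 1.56
params.KT1 = 0.25
params.KT2 = 0.25
params.KET1 = 0.25
params.KET2 = 0.25
params.KER1 = 0.25
params.KER2 = 0.25
params.alphaR1 = 0.2
params.alphaR2 = 0.2
params.betaR1 = 0.8
params.betaR2 = 0.8
params.betaT1 = 0.8
params.betaT2 = 0.8
params.betaE1 = 0.8
params.betaE2 = 0.8

init.xDOC = 61.1
init.xNO3 = 18.3
init.xNO2 = 0
init.xN2 = 0
init.xDIC = 1
init.xBM = 1.5
init.rho1 = 0.001
init.rho2 = 0.001
init.tau1 = 0.001
init.tau2 = 0.001
init.e1 = 0.001
init.e2 = 0.001
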