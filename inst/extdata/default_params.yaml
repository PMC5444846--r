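# Baseline parameter set of the tumor-immune combination-therapy model.
# Flat key -> value; units as documented in ?default_parameters.
delta_D: 8.64e-7
delta_T: 8.64e-7
delta_C: 8.64e-7
delta_G: 9.8495e-2
delta_I12: 6.0472e-2
delta_I2: 9.9956e-2
delta_A: 7.85e-2
sigma0: 1.0
lambda_DC: 0.364
lambda_DG: 20.02
lambda_T1I12: 4.66
lambda_T1I2: 0.25
lambda_T8I12: 4.15
lambda_T8I2: 0.25
lambda_C: 0.616
lambda_G: 2.23e-10
lambda_I12D: 5.18e-7
lambda_I2T1: 2.82e-8
eta1: 11.5
eta8: 46.0
mu_PA: 6.87e6
rho_P: 2.49e-7
rho_L: 5.22e-7
epsilon: 0.01
d_D: 0.1
d_T1: 0.197
d_T8: 0.18
d_C: 0.17
d_G: 1.28
d_I12: 1.38
d_I2: 2.376
d_A: 0.0462
K_G: 1.74e-9
K_C: 0.4
K_I12: 1.5e-10
K_I2: 2.37e-11
Kp_TQ: 1.365e-18
K_D: 4.0e-4
K_T1: 2.0e-3
K_T8: 1.0e-3
D_0: 2.0e-5
T_10: 4.0e-4
T_80: 2.0e-4
C_M: 0.8
That_1: 4.0e-3
That_8: 2.0e-3
theta_tot: 0.4034
lambda0: 0.069
tcell_floor: 1.0e-12
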