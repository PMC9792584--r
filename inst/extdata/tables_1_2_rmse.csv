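group,subject,sesc_ap,sesc_ml,segmental_ap,segmental_ml
fit,1,14.08,21.78,50.62,71.24
fit,2,19.98,15.28,43.31,39.20
fit,3,26.33,19.65,118.80,17.11
fit,4,22.70,14.81,53.06,16.07
fit,5,9.42,11.34,44.91,17.49
fit,6,32.44,18.95,53.01,42.04
fit,7,21.38,15.15,23.46,33.11
fit,8,14.68,11.68,46.18,29.77
fit,9,13.17,17.86,49.86,19.82
fit,10,19.43,19.89,45.23,31.16
fit,11,14.83,21.34,37.71,31.51
obese,1,8.60,8.33,38.62,40.73
obese,2,12.28,12.52,56.45,19.93
obese,3,20.16,12.08,23.42,14.03
obese,4,14.00,24.32,26.89,31.93
obese,5,21.26,17.22,45.15,29.86
obese,6,17.47,68.12,21.79,51.05
obese,7,13.53,11.60,53.29,20.63
obese,8,36.35,34.77,61.03,52.47
obese,9,13.74,28.98,29.40,32.13
obese,10,18.39,18.78,44.16,20.50
obese,11,22.42,20.58,32.35,33.30
obese,12,13.77,21.42,43.00,23.78
obese,13,16.78,15.27,28.82,19.31
obese,14,26.05,35.75,34.88,30.23
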