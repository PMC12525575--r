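# Published per-sample 1H relaxation markers for 19 lung-tissue samples
# (patients P1-P10; (t) tumor, (r) peri-tumoral reference).
# alpha: power-law exponent of the R1 dispersion (10 kHz - 18.7 MHz).
# xi: percent drop of R1 between 10 kHz and 100 kHz.
# r2_slow, r2_fast: bi-exponential CPMG rates at 18.7 MHz, 1/s.
# amp_ratio: 100 * Afast/Aslow. rate_ratio and r2slow_over_r1 as printed.
# Values and uncertainties stored exactly as printed.
sample_id,group,alpha,alpha_err,xi,r2_slow,r2_slow_err,r2_fast,r2_fast_err,amp_ratio,rate_ratio,r2slow_over_r1
P1 (r),reference,0.30,0.01,48,10.8,0.1,24.1,0.77,46,2.2,6.4
P1 (t),tumor,0.33,0.01,54,5.6,0.2,15.3,0.20,36,2.7,2.7
P2 (r),reference,0.28,0.01,43,11.99,0.04,37.1,0.89,26,3.1,6.1
P2 (t),tumor,0.32,0.01,55,6.4,0.1,12.4,0.11,38,1.9,4.6
P3 (r),reference,0.33,0.01,59,7.5,0.1,22.26,0.04,46,3.0,3.2
P3 (t),tumor,0.31,0.01,53,10.11,0.08,31.4,0.3,61,3.2,4.7
P4 (r),reference,0.33,0.01,50,10.9,0.1,37.3,0.7,81,3.4,7.0
P4 (t),tumor,0.30,0.01,51,7.62,0.06,22.5,0.2,48,2.9,5.4
P5 (r),reference,0.29,0.01,44,6.72,0.05,15.5,0.2,66,2.3,4.9
P5 (t),tumor,0.29,0.01,49,2.37,0.02,11.04,0.04,20,4.7,1.7
P6 (r),reference,0.29,0.01,52,6.61,0.08,16.1,0.1,36,2.4,4.4
P6 (t),tumor,0.30,0.01,53,7.49,0.03,18.2,0.2,76,2.4,5.1
P7 (r),reference,0.28,0.01,49,6.68,0.04,18.8,0.2,88,2.8,4.5
P7 (t),tumor,0.33,0.01,58,5.91,0.06,28.8,0.1,19,4.9,2.7
P8 (r),reference,0.27,0.01,47,3.91,0.04,12.8,0.1,27,3.3,2.9
P8 (t),tumor,0.29,0.01,51,2.95,0.02,8.40,0.04,35,2.9,2.8
P9 (r),reference,0.33,0.01,51,4.18,0.04,11.89,0.05,21,2.8,3.4
P9 (t),tumor,0.30,0.01,48,4.38,0.03,14.6,0.1,34,3.3,2.9
P10 (t),tumor,0.33,0.01,52,10.1,0.1,18.8,0.2,66,1.9,5.2
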