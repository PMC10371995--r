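# Complex refractive index of bulk gold, m = n + i k, 400-1400 nm.
# Values transcribed (rounded) from the tabulated thin-film measurements of
# Johnson & Christy, Phys. Rev. B 6, 4370 (1972), converted from photon
# energy to vacuum wavelength. Intended for log-wavelength linear
# interpolation (see goldDielectric()). Column 1: wavelength (nm);
# column 2: n; column 3: k (imaginary part, >= 0 for a passive metal).
wavelength_nm	n	k
397.4	1.62	1.95
413.3	1.54	1.90
430.5	1.45	1.87
450.9	1.40	1.88
471.4	1.31	1.89
495.9	1.04	1.83
520.9	0.62	2.08
548.6	0.43	2.46
582.1	0.29	2.86
616.8	0.21	3.27
659.5	0.14	3.61
704.4	0.13	4.10
756.0	0.14	4.54
821.1	0.16	5.03
892.0	0.17	5.66
984.0	0.22	6.35
1088.0	0.27	7.15
1216.0	0.33	8.15
1393.0	0.39	9.52
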