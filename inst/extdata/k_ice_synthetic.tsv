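# Spectral absorption coefficient of bare first-year sea ice, 200-1000 nm.
# Author-constructed SYNTHETIC representative table (blue transmission
# maximum near 450-500 nm, strong UV and red/near-infrared absorption),
# shaped after published interior-ice observations; replace with a measured
# table for production use. Columns: wavelength_nm, k_per_m.
wavelength_nm	k_per_m
200	4.0
250	2.6
300	1.8
350	1.3
400	1.0
450	0.82
500	0.80
550	0.95
600	1.3
650	1.8
700	2.5
750	3.9
800	5.5
850	7.4
900	10.0
950	14.0
1000	20.0
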