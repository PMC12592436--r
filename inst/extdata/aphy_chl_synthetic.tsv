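# Chlorophyll-a specific absorption of phytoplankton, m^2 (mg chl)^-1.
# Author-constructed SYNTHETIC representative table with the canonical blue
# (440 nm) and red (676 nm) absorption peaks and a moderate UV shoulder;
# replace with a measured table for production use.
# Columns: wavelength_nm, aphy_m2_per_mg.
wavelength_nm	aphy_m2_per_mg
280	0.030
300	0.028
320	0.025
340	0.023
360	0.022
380	0.024
400	0.030
420	0.036
440	0.039
460	0.034
480	0.028
500	0.021
520	0.014
540	0.010
560	0.0075
580	0.0065
600	0.0068
620	0.0078
640	0.0082
660	0.014
676	0.0205
690	0.012
700	0.0055
710	0.002
750	0.0
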