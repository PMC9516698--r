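# Synthetic calibrant reference set (polyalanine-like ladder) generated from
# the package's default instrument model; drift times rounded to 0.1 us.
# Replace with an instrument-specific table for real data.
mz	charge	reference_ccs	measured_dt
302.16	1	165.4	2.1741
433.23	1	203.7	3.2499
575.31	1	236.2	4.3118
716.38	1	266.0	5.3957
858.46	1	293.1	6.4727
999.54	1	318.3	7.5501
1140.61	1	341.9	8.6246
1281.69	1	364.2	9.6974
650.35	2	390.5	3.1253
900.47	2	452.8	4.1117
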