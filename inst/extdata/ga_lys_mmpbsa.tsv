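# MM-PBSA energy components for the gallic acid-lysozyme complex (kJ/mol),
# as published; reported aggregate columns retained for the consistency audit
T	vdw	elec	pol_solv	nonpol_solv	solv	gas	total
298	-44.92	-24.22	58.98	-1.79	57.20	-69.13	-11.93
310	-35.36	-52.48	81.42	-1.14	80.28	-87.84	-7.56
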