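# SYNTHETIC overlay of per-drug disposition parameters.
# The quantitative-validation scenarios need plasma clearance (CL_p, L/h),
# subcutaneous bioavailability (F, fraction) and a blood/plasma ratio (BP).
# The values below are literature-typical estimates assembled for this
# package (they are NOT a published reference table): Etanercept CL_p from
# reported intravenous clearance ~0.072 L/h and absolute SC bioavailability
# ~58%; IGF-1 CL_p from a whole-body clearance of ~0.29 mL/min/kg scaled to
# the 80.7 kg reference individual, with near-complete SC bioavailability.
# BP = 1 treats the blood pool as plasma (no red-cell partitioning data).
protein	CL_p	BP	F	source
Etanercept	0.072	1	0.58	synthetic_literature_estimate
IGF-1	1.40	1	1.0	synthetic_literature_estimate
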