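# Primary radiolytic yields for low-LET (gamma) radiolysis of pure water,
# in molecules per 100 eV absorbed. Standard compilation values
# (e.g. Spinks & Woods, An Introduction to Radiation Chemistry).
# O2 is a secondary product formed downstream of the primary species;
# its direct primary yield is ~0 and oxygen budgets should be computed
# from the peroxide/radical chemistry, not from this row.
species	g_value
H2	0.45
H2O2	0.68
OH	2.70
e_aq	2.60
H	0.60
O2	0.00
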