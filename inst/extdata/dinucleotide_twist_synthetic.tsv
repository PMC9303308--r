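step	twist_deg	stiffness
AA	35.35	85
AC	33.35	80
AG	32.95	70
AT	32.55	98
CA	35.15	52
CC	33.95	78
CG	34.75	58
CT	32.95	70
GA	34.75	66
GC	34.15	72
GG	33.95	78
GT	33.35	80
TA	31.55	45
TC	34.75	66
TG	35.15	52
TT	35.35	85
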