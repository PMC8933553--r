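# Auxiliary words/phrases removed from adverse-event terms.
# Literal phrases match whole token spans, case-insensitively.
# Placeholders: <number> = integer/decimal, <time-unit> = second..year (+s).
baseline phase
treatment phase
follow-up phase
left
right
bilateral
for <number> <time-unit>
after <number> <time-unit>
within <number> <time-unit>
at <number> <time-unit>
day <number>
week <number>
cycle <number>
grade <number>
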