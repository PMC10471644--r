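# Reference one-way partition (degrees of freedom and sums of squares) of
# log(x+1)-transformed PUFA mass fractions among littoral invertebrate taxa,
# from the 25-lake fatty-acid survey (243 samples, 24 taxon groups).
# Used as input for worked-example pseudo-F arithmetic; the raw per-sample
# mass fractions behind this partition are not publicly deposited.
pufa,source,df,ss
ARA,taxa,23,11.755
ARA,residual,219,33.038
ARA,total,242,44.792
EPA,taxa,23,27.028
EPA,residual,219,70.358
EPA,total,242,97.387
DHA,taxa,23,10.601
DHA,residual,219,4.8207
DHA,total,242,15.422
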