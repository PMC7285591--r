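# Five-group partition of the 20 amino acids for grouped amino acid
# composition: aliphatic, aromatic, positively charged, negatively charged,
# uncharged (iFeature conventions).
group	letters
aliphatic	GAVLMI
aromatic	FYW
positive_charge	KRH
negative_charge	DE
uncharged	STCPNQ
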