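# Main T4aP locus family order used by the synthetic-genome generator,
# one family per line, genomic left-to-right order.  The locus carries 17
# genes: the core machinery, two pilRS two-component pairs (detected as the
# combined family pilRS and resolved positionally into pilR1S1/pilR2S2),
# pilGHI and tsaP.  pilB sits at the anchor-proximal end: the riboflavin
# kinase gene ribF is placed immediately after it, outside the cluster.
# Edit this file to emulate a different locus; downstream code keys on
# counts and family sets, not on this exact order.
pilQ
pilP
pilO
pilN
pilM
tsaP
pilI
pilH
pilG
pilRS
pilRS
pilRS
pilRS
pilA
pilC
pilT
pilB
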