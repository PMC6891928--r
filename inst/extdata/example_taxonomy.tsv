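otu_id	lineage
OTU0001	k__Bacteria; p__Actinobacteria; c__; o__; f__; g__; s__OTU0001
OTU0002	k__Bacteria; p__Bacteroidetes; c__; o__; f__; g__; s__OTU0002
OTU0003	k__Bacteria; p__Firmicutes; c__; o__; f__; g__; s__OTU0003
OTU0004	k__Bacteria; p__Fusobacteria; c__; o__; f__; g__; s__OTU0004
OTU0005	k__Bacteria; p__Proteobacteria; c__; o__; f__; g__; s__OTU0005
OTU0006	k__Bacteria; p__Actinobacteria; c__; o__; f__; g__; s__OTU0006
OTU0007	k__Bacteria; p__Bacteroidetes; c__; o__; f__; g__; s__OTU0007
OTU0008	k__Bacteria; p__Firmicutes; c__; o__; f__; g__; s__OTU0008
OTU0009	k__Bacteria; p__Fusobacteria; c__; o__; f__; g__; s__OTU0009
OTU0010	k__Bacteria; p__Proteobacteria; c__; o__; f__; g__; s__OTU0010
OTU0011	k__Bacteria; p__Actinobacteria; c__; o__; f__; g__; s__OTU0011
OTU0012	k__Bacteria; p__Bacteroidetes; c__; o__; f__; g__; s__OTU0012
OTU0013	k__Bacteria; p__Firmicutes; c__; o__; f__; g__; s__OTU0013
OTU0014	k__Bacteria; p__Fusobacteria; c__; o__; f__; g__; s__OTU0014
OTU0015	k__Bacteria; p__Proteobacteria; c__; o__; f__; g__; s__OTU0015
OTU0016	k__Bacteria; p__Actinobacteria; c__; o__; f__; g__; s__OTU0016
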