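sequence_id	species_id	superkingdom	phylum	class	order	family	genus
seq01	spA	Bacteria	Actinobacteria	Actinomycetia	Mycobacteriales	Mycobacteriaceae	Mycolicibacterium
seq02	spA	Bacteria	Actinobacteria	Actinomycetia	Mycobacteriales	Mycobacteriaceae	Mycolicibacterium
seq03	spA	Bacteria	Actinobacteria	Actinomycetia	Mycobacteriales	Mycobacteriaceae	Mycolicibacterium
seq04	spB	Bacteria	Actinobacteria	Actinomycetia	Micrococcales	Micrococcaceae	Arthrobacter
seq05	spC	Bacteria	Proteobacteria	Gammaproteobacteria	Enterobacterales	Enterobacteriaceae	Escherichia
seq06	spC	Bacteria	Proteobacteria	Gammaproteobacteria	Enterobacterales	Enterobacteriaceae	Escherichia
seq07	spD	Bacteria	Firmicutes	Bacilli	Bacillales	Bacillaceae	Bacillus
seq08	spE	Bacteria	Firmicutes	Clostridia	Eubacteriales	Clostridiaceae	Clostridium
seq09	spF	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Bacteroidaceae	Bacteroides
seq10	spF	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Bacteroidaceae	Bacteroides
seq11	spG	Archaea	Euryarchaeota	Halobacteria	Halobacteriales	Halobacteriaceae	Halobacterium
seq12	spG	Archaea	Euryarchaeota	Halobacteria	Halobacteriales	Halobacteriaceae	Halobacterium
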