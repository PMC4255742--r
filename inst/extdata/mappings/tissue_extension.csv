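# Example extension mapping: where a study table juxtaposes
# Characteristics[OBI:organism] and Characteristics[OBI:tissue specimen],
# add the specific relationship that the tissue is part of the organism.
Characteristics[OBI:tissue specimen],tissue,http://purl.obolibrary.org/obo/OBI_0001479, is part of, http://purl.obolibrary.org/obo/BFO_0000050, organism, Characteristics[OBI:organism]
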