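# ISA-OBI mapping: relates ISA syntactic elements to classes of the
# Ontology for Biomedical Investigations (and BFO). A Protocol REF in a
# study file denotes OBI:material processing; in an assay file it denotes
# the more generic OBI:planned process (it may yield material, data, or
# transform data). Elements without a row here fall back to the ISA
# vocabulary mapping loaded underneath.
Investigation,investigation,http://purl.obolibrary.org/obo/OBI_0000066
Study Assay,assay,http://purl.obolibrary.org/obo/OBI_0000070
Protocol REF,material processing,http://purl.obolibrary.org/obo/OBI_0000094,STUDY
Protocol REF,planned process,http://purl.obolibrary.org/obo/OBI_0000011,ASSAY
Protocol,plan,http://purl.obolibrary.org/obo/OBI_0000260
Characteristics[OBI:organism],organism,http://purl.obolibrary.org/obo/OBI_0100026
Source Name,material entity,http://purl.obolibrary.org/obo/BFO_0000040
Sample Name,specimen,http://purl.obolibrary.org/obo/OBI_0100051
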