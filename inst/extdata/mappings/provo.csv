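# ISA-PROV-O mapping: provenance view of an ISA dataset. Materials and data
# are prov:Entity, protocol applications are prov:Activity, protocols are
# prov:Plan. Elements without a row fall back to the ISA vocabulary mapping.
Source Name,entity,http://www.w3.org/ns/prov#Entity
Sample Name,entity,http://www.w3.org/ns/prov#Entity
Extract Name,entity,http://www.w3.org/ns/prov#Entity
Labeled Extract Name,entity,http://www.w3.org/ns/prov#Entity
Raw Data File,entity,http://www.w3.org/ns/prov#Entity
Derived Data File,entity,http://www.w3.org/ns/prov#Entity
Data File,entity,http://www.w3.org/ns/prov#Entity
Protocol REF,activity,http://www.w3.org/ns/prov#Activity
Protocol,plan,http://www.w3.org/ns/prov#Plan
Investigation,collection,http://www.w3.org/ns/prov#Collection
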