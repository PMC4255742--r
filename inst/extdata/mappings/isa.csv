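# ISA-ISA mapping: a one-to-one relationship from the ISA-Tab syntactic
# vocabulary to an ISA vocabulary namespace. The ISA ontology IRIs are
# project-configurable stand-ins under http://purl.org/isaterms/; override
# any row by loading a later mapping file.
# type rows: isa element, class label, class IRI[, context]
Investigation,ISA dataset,http://purl.org/isaterms/Investigation
Study,study,http://purl.org/isaterms/Study
Study Assay,assay,http://purl.org/isaterms/Assay
Study Design,study design,http://purl.org/isaterms/StudyDesign
Study Factor,study factor,http://purl.org/isaterms/StudyFactor
Study Group,study group,http://purl.org/isaterms/StudyGroup
Factor Value,factor value,http://purl.org/isaterms/FactorValue
Source Name,source,http://purl.org/isaterms/Source
Sample Name,sample,http://purl.org/isaterms/Sample
Extract Name,extract,http://purl.org/isaterms/Extract
Labeled Extract Name,labeled extract,http://purl.org/isaterms/LabeledExtract
Raw Data File,raw data file,http://purl.org/isaterms/RawDataFile
Derived Data File,derived data file,http://purl.org/isaterms/DerivedDataFile
Data File,data file,http://purl.org/isaterms/DataFile
Protocol REF,protocol application,http://purl.org/isaterms/ProtocolApplication
Protocol,protocol,http://purl.org/isaterms/Protocol
Characteristics,characteristic,http://purl.org/isaterms/Characteristic
Parameter Value,parameter value,http://purl.org/isaterms/ParameterValue
Unit,unit,http://purl.org/isaterms/Unit
Label,label,http://purl.org/isaterms/MaterialLabel
Comment,comment,http://purl.org/isaterms/Comment
Material,material,http://purl.org/isaterms/Material
# predicate vocabulary used by the conversion engine (overridable per
# framework like any type row)
has study,has study,http://purl.org/isaterms/has_study
has assay,has assay,http://purl.org/isaterms/has_assay
has design,has design,http://purl.org/isaterms/has_design
has factor,has factor,http://purl.org/isaterms/has_factor
has level,has level,http://purl.org/isaterms/has_level
has group,has group,http://purl.org/isaterms/has_group
has member,has member,http://purl.org/isaterms/has_member
has size,has size,http://purl.org/isaterms/has_size
has input,has input,http://purl.org/isaterms/has_input
has output,has output,http://purl.org/isaterms/has_output
executes protocol,executes protocol,http://purl.org/isaterms/executes_protocol
has characteristic,has characteristic,http://purl.org/isaterms/has_characteristic
has parameter value,has parameter value,http://purl.org/isaterms/has_parameter_value
has unit,has unit,http://purl.org/isaterms/has_unit
has value,has value,http://purl.org/isaterms/has_value
has protocol,has protocol,http://purl.org/isaterms/has_protocol
# default balanced-design class; replace with the STATO term via a later
# mapping file or the --balanced-class flag
balanced design,balanced design,http://purl.org/isaterms/BalancedDesign
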