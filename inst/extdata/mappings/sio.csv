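# ISA-SIO mapping (skeletal): supports interoperability with SIO-annotated
# resources such as Bio2RDF. Only broadly applicable SIO classes are listed;
# everything else falls back to the ISA vocabulary mapping. Extend with a
# later mapping file for finer typing.
Protocol REF,process,http://semanticscience.org/resource/SIO_000006
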