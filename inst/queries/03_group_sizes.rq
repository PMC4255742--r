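# Nature and sizes of the study groups (combinations of factor values).
PREFIX rdfs:  <http://www.w3.org/2000/01/rdf-schema#>
PREFIX isa:   <http://purl.org/isaterms/>

SELECT ?study ?combination ?size
WHERE {
  ?dataset isa:has_study ?s .
  ?s isa:has_group ?g .
  ?g isa:has_size ?size .
  ?g rdfs:label ?combination .
  ?s rdfs:label ?study .
}
ORDER BY ?study ?combination
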