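# Is the study design balanced? True when the minimum group size equals
# the maximum group size.
PREFIX rdfs:  <http://www.w3.org/2000/01/rdf-schema#>
PREFIX isa:   <http://purl.org/isaterms/>

SELECT ?study ((MIN(?size) = MAX(?size)) AS ?balanced)
WHERE {
  ?dataset isa:has_study ?s .
  ?s isa:has_group ?g .
  ?g isa:has_size ?size .
  ?s rdfs:label ?study .
}
GROUP BY ?study
ORDER BY ?study
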