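# Minimum and maximum study-group sizes per study.
PREFIX rdfs:  <http://www.w3.org/2000/01/rdf-schema#>
PREFIX isa:   <http://purl.org/isaterms/>

SELECT ?study (MIN(?size) AS ?min_size) (MAX(?size) AS ?max_size)
WHERE {
  ?dataset isa:has_study ?s .
  ?s isa:has_group ?g .
  ?g isa:has_size ?size .
  ?s rdfs:label ?study .
}
GROUP BY ?study
ORDER BY ?study
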