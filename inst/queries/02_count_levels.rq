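# Count the number of distinct levels per factor, for each study.
PREFIX rdfs:  <http://www.w3.org/2000/01/rdf-schema#>
PREFIX isa:   <http://purl.org/isaterms/>

SELECT ?study ?factor (COUNT(DISTINCT ?l) AS ?n_levels)
WHERE {
  ?dataset isa:has_study ?s .
  ?s isa:has_factor ?f .
  ?f isa:has_level ?l .
  ?s rdfs:label ?study .
  ?f rdfs:label ?factor .
}
GROUP BY ?study ?factor
ORDER BY ?study ?factor
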