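# Retrieve each study factor and its associated discrete levels, per study.
PREFIX rdfs:  <http://www.w3.org/2000/01/rdf-schema#>
PREFIX isa:   <http://purl.org/isaterms/>

SELECT ?study ?factor ?level
WHERE {
  ?dataset isa:has_study ?s .
  ?s isa:has_factor ?f .
  ?f isa:has_level ?l .
  ?s rdfs:label ?study .
  ?f rdfs:label ?factor .
  ?l rdfs:label ?level .
}
ORDER BY ?study ?factor ?level
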