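# Materialise the balanced-design annotation: type the study-design
# individual of every balanced study with the balanced-design class.
# Replace isa:BalancedDesign with the STATO balanced-design term when
# available in your mapping set.
PREFIX rdf:   <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX isa:   <http://purl.org/isaterms/>

CONSTRUCT { ?d rdf:type isa:BalancedDesign . }
WHERE {
  {
    SELECT ?s (MIN(?size) AS ?min_size) (MAX(?size) AS ?max_size)
    WHERE {
      ?s isa:has_group ?g .
      ?g isa:has_size ?size .
    }
    GROUP BY ?s
  }
  FILTER (?min_size = ?max_size)
  ?s isa:has_design ?d .
}
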