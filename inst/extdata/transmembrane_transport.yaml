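pattern_name: transmembrane_transport
pattern_iri: http://example.org/patterns/transmembrane_transport.yaml
extends: obo
description: >-
  Classes of transport of a cargo entity across a membrane, defined by the
  type of cargo and the type of membrane crossed. Instantiated classes are
  auto-classified by the cargo and membrane hierarchies of the reference
  ontology.
classes:
  transport: EX:0000001
  chemical entity: EX:0000002
  amino acid: EX:0000003
  transcript: EX:0000007
  membrane: EX:0000008
relations:
  transports: EX:2000001
  crosses: EX:2000002
vars:
  cargo: "'chemical entity' or 'transcript'"
  membrane: "'membrane'"
data_list_vars:
  def_dbxref: xsd:string
name:
  text: "%s transport across the %s"
  vars:
    - cargo
    - membrane
def:
  text: "The directed movement of %s across the %s."
  vars:
    - cargo
    - membrane
  xrefs: def_dbxref
equivalentTo:
  text: "'transport' and ('transports' some %s) and ('crosses' some %s)"
  vars:
    - cargo
    - membrane
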