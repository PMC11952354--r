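{
  "nodes_file": "nodes.tsv",
  "edges_file": "edges.tsv",
  "endpoint_name": "demo",
  "schema_file": "../demo_schema.yaml",
  "kg_version": "demo-1.0",
  "trapi_attribute_map": {
    "publications": {
      "attribute_type_id": "biolink:publications"
    }
  }
}
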