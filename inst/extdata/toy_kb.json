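{
  "molecules": [
    {
      "id": "a",
      "kind": "gene",
      "name": "TF-a",
      "species": []
    },
    {
      "id": "b",
      "kind": "metabolite",
      "name": "substrate-b",
      "species": []
    },
    {
      "id": "c",
      "kind": "metabolite",
      "name": "substrate-c",
      "species": []
    },
    {
      "id": "d",
      "kind": "metabolite",
      "name": "product-d",
      "species": []
    },
    {
      "id": "e",
      "kind": "protein",
      "name": "enzyme-e",
      "species": []
    },
    {
      "id": "g",
      "kind": "gene",
      "name": "gene-g",
      "species": []
    }
  ],
  "reactions": [
    {
      "id": "effect_a_act_g",
      "substrates": [],
      "products": ["g"],
      "activators": ["a"],
      "inhibitors": [],
      "modulators": [],
      "reversible": false,
      "species": []
    },
    {
      "id": "r2",
      "substrates": ["b", "c"],
      "products": ["d"],
      "activators": ["e"],
      "inhibitors": [],
      "modulators": [],
      "reversible": false,
      "species": []
    }
  ]
}
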