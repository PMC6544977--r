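{
  "name": "toy_two_gene",
  "version": "1",
  "substances": [
    {
      "id": "s1",
      "role": "protein"
    },
    {
      "id": "s2",
      "role": "protein"
    }
  ],
  "sites": [
    {
      "id": "b1",
      "ligands": [
        "s1"
      ]
    },
    {
      "id": "b2",
      "ligands": [
        "s2"
      ]
    },
    {
      "id": "b3",
      "ligands": [
        "s2"
      ]
    }
  ],
  "control_functions": [
    {
      "id": "f1",
      "inputs": [
        "b1",
        "b2"
      ],
      "table": [
        {
          "state_tuple": [
            "BOUND:s1",
            "BOUND:s2"
          ],
          "level": 0
        },
        {
          "state_tuple": [
            "BOUND:s1",
            "FREE"
          ],
          "level": 0
        },
        {
          "state_tuple": [
            "FREE",
            "BOUND:s2"
          ],
          "level": 1
        },
        {
          "state_tuple": [
            "FREE",
            "FREE"
          ],
          "level": 0
        }
      ]
    },
    {
      "id": "f2",
      "inputs": [
        "b3"
      ],
      "table": [
        {
          "state_tuple": [
            "BOUND:s2"
          ],
          "level": 0
        },
        {
          "state_tuple": [
            "FREE"
          ],
          "level": 1
        }
      ]
    }
  ],
  "generators": [
    {
      "id": "s1",
      "product": "s1",
      "control": "f1",
      "rates": {
        "growth": 1,
        "degradation": 1
      }
    },
    {
      "id": "s2",
      "product": "s2",
      "control": "f2",
      "rates": {
        "growth": 1,
        "degradation": 1
      }
    }
  ]
}
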