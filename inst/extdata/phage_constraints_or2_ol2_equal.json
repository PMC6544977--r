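{
  "Cro": {
    "chains": [
      [
        "bOR3.dis",
        "bOR3.as",
        "bOR2.dis",
        "bOR2.as",
        "bOR1.dis",
        "bOR1.as"
      ],
      [
        "bOL3.dis",
        "bOL3.as",
        "bOL2.dis",
        "bOL2.as",
        "bOL1.dis",
        "bOL1.as"
      ]
    ],
    "adjacency_blocks": [
      [
        "bOR1.dis",
        "bOR1.as"
      ],
      [
        "bOR2.dis",
        "bOR2.as"
      ],
      [
        "bOR3.dis",
        "bOR3.as"
      ],
      [
        "bOL1.dis",
        "bOL1.as"
      ],
      [
        "bOL2.dis",
        "bOL2.as"
      ],
      [
        "bOL3.dis",
        "bOL3.as"
      ]
    ],
    "permitted_interleavings": [],
    "equalities": [
      [
        "bOR2.dis",
        "bOL2.dis"
      ],
      [
        "bOR2.as",
        "bOL2.as"
      ]
    ]
  },
  "repressor": {
    "chains": [
      [
        "bOR1.dis",
        "bOR1.as",
        "bOR2.dis",
        "bOR2.as",
        "bOR3.dis",
        "bOR3.as"
      ],
      [
        "bOL1.dis",
        "bOL1.as",
        "bOL2.dis",
        "bOL2.as",
        "bOL3.dis",
        "bOL3.as"
      ]
    ],
    "adjacency_blocks": [
      [
        "bOR1.dis",
        "bOR1.as"
      ],
      [
        "bOR2.dis",
        "bOR2.as"
      ],
      [
        "bOR3.dis",
        "bOR3.as"
      ],
      [
        "bOL1.dis",
        "bOL1.as"
      ],
      [
        "bOL2.dis",
        "bOL2.as"
      ],
      [
        "bOL3.dis",
        "bOL3.as"
      ]
    ],
    "permitted_interleavings": [],
    "equalities": [
      [
        "bOR2.dis",
        "bOL2.dis"
      ],
      [
        "bOR2.as",
        "bOL2.as"
      ]
    ]
  },
  "CII": {
    "chains": [
      [
        "bCII-2.dis",
        "bCII-2.as",
        "bCII-1.dis",
        "bCII-1.as"
      ]
    ],
    "adjacency_blocks": [
      [
        "bCII-2.dis",
        "bCII-2.as"
      ],
      [
        "bCII-1.dis",
        "bCII-1.as"
      ]
    ],
    "permitted_interleavings": [],
    "equalities": []
  }
}
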