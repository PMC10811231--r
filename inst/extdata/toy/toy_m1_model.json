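{
  "Model": {
    "Name": "toy_m1_macrophage",
    "Variables": [
      {
        "Id": 1,
        "Name": "IFNG",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": ""
      },
      {
        "Id": 2,
        "Name": "LPS",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": ""
      },
      {
        "Id": 3,
        "Name": "GF",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": ""
      },
      {
        "Id": 4,
        "Name": "IL10",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": ""
      },
      {
        "Id": 5,
        "Name": "IFNGR",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "var(1)"
      },
      {
        "Id": 6,
        "Name": "TLR4",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "var(2)"
      },
      {
        "Id": 7,
        "Name": "JAK1",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "var(5)"
      },
      {
        "Id": 8,
        "Name": "JAK2",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "var(5)"
      },
      {
        "Id": 9,
        "Name": "STAT1",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "min(var(5), max(var(7), var(8)))"
      },
      {
        "Id": 10,
        "Name": "NFkB",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "max(var(6), var(9))"
      },
      {
        "Id": 11,
        "Name": "ERK",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "var(3)"
      },
      {
        "Id": 12,
        "Name": "IL10R",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "var(4)"
      },
      {
        "Id": 13,
        "Name": "STAT3",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "var(12)"
      },
      {
        "Id": 14,
        "Name": "TNF",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "var(10)"
      },
      {
        "Id": 15,
        "Name": "Proliferation_M1_macrophage",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "min(var(10), var(11), 1 - var(13))"
      },
      {
        "Id": 16,
        "Name": "Apoptosis_M1_macrophage",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "1 - var(10)"
      },
      {
        "Id": 17,
        "Name": "Inflammation_signal",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": "var(14)"
      }
    ],
    "Relationships": [
      {
        "Id": 1,
        "FromVariable": 1,
        "ToVariable": 5,
        "Type": "Activator"
      },
      {
        "Id": 2,
        "FromVariable": 2,
        "ToVariable": 6,
        "Type": "Activator"
      },
      {
        "Id": 3,
        "FromVariable": 5,
        "ToVariable": 7,
        "Type": "Activator"
      },
      {
        "Id": 4,
        "FromVariable": 5,
        "ToVariable": 8,
        "Type": "Activator"
      },
      {
        "Id": 5,
        "FromVariable": 5,
        "ToVariable": 9,
        "Type": "Activator"
      },
      {
        "Id": 6,
        "FromVariable": 7,
        "ToVariable": 9,
        "Type": "Activator"
      },
      {
        "Id": 7,
        "FromVariable": 8,
        "ToVariable": 9,
        "Type": "Activator"
      },
      {
        "Id": 8,
        "FromVariable": 6,
        "ToVariable": 10,
        "Type": "Activator"
      },
      {
        "Id": 9,
        "FromVariable": 9,
        "ToVariable": 10,
        "Type": "Activator"
      },
      {
        "Id": 10,
        "FromVariable": 3,
        "ToVariable": 11,
        "Type": "Activator"
      },
      {
        "Id": 11,
        "FromVariable": 4,
        "ToVariable": 12,
        "Type": "Activator"
      },
      {
        "Id": 12,
        "FromVariable": 12,
        "ToVariable": 13,
        "Type": "Activator"
      },
      {
        "Id": 13,
        "FromVariable": 10,
        "ToVariable": 14,
        "Type": "Activator"
      },
      {
        "Id": 14,
        "FromVariable": 10,
        "ToVariable": 15,
        "Type": "Activator"
      },
      {
        "Id": 15,
        "FromVariable": 11,
        "ToVariable": 15,
        "Type": "Activator"
      },
      {
        "Id": 16,
        "FromVariable": 13,
        "ToVariable": 15,
        "Type": "Inhibitor"
      },
      {
        "Id": 17,
        "FromVariable": 10,
        "ToVariable": 16,
        "Type": "Inhibitor"
      },
      {
        "Id": 18,
        "FromVariable": 14,
        "ToVariable": 17,
        "Type": "Activator"
      }
    ]
  }
}
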