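{
  "description": "Transcribed summary tables of the emulated profiling study. Fold inductions are kept at the printed two-decimal precision; where two source tables print slightly different values for the same quantity, both are retained under their source_table tags.",
  "files": [
    {
      "name": "table2_mirnas",
      "file": "table2_mirnas.tsv",
      "md5": "3f22ecad24c94708f6323f0657253517"
    },
    {
      "name": "table3_recurrent",
      "file": "table3_recurrent.tsv",
      "md5": "91ac0188feff25b4624338ad335f94ba"
    },
    {
      "name": "table4_pairs",
      "file": "table4_pairs.tsv",
      "md5": "b6f4bb3a37c3a5654fdb6573d64ccb30"
    },
    {
      "name": "table5_146b_targets",
      "file": "table5_146b_targets.tsv",
      "md5": "1f791c3ea5eb788be76c535c09413643"
    }
  ]
}
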