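# Literature-derived IL-13 responder genes (editable asset).
# The data-derived IL-13 signature is small; these well-established
# IL-13/type-2 response genes of keratinocytes supplement it.  This list
# is a synthetic stand-in assembled from the general atopic-dermatitis
# literature, not a reproduction of any specific published supplement.
IL13:
  - CCL26
  - CA2
  - NTRK1
  - SERPINB3
  - SERPINB4
  - SERPINB13
  - CISH
  - HSD3B1
  - POSTN
  - LOXL4
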