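# Default logical-subunit -> chain assignments for the deposited Cas1-Cas2
# entries. The positional labels (Cas1a vs Cas1a', etc.) cannot be inferred
# from a coordinate file; they are a convention, and these defaults are a
# starting point derived from the entries' depositor chain ordering. ALWAYS
# verify against the structure you downloaded (biological assembly versus
# asymmetric unit differ for some entries) and edit as needed: this file is
# configuration, not code.
#
# Keys: Cas1a, Cas1b, Cas1ap, Cas1bp (primed copies), Cas2, Cas2p,
#       DNA_alpha, DNA_beta.
4P6I:
  Cas1a: [A]
  Cas1b: [B]
  Cas1ap: [C]
  Cas1bp: [D]
  Cas2: [E]
  Cas2p: [F]
5DLJ:
  Cas1a: [A]
  Cas1b: [B]
  Cas1ap: [C]
  Cas1bp: [D]
  Cas2: [E]
  Cas2p: [F]
  DNA_alpha: [G]
  DNA_beta: [H]
5DQZ:
  Cas1a: [A]
  Cas1b: [B]
  Cas1ap: [C]
  Cas1bp: [D]
  Cas2: [E]
  Cas2p: [F]
  DNA_alpha: [G]
  DNA_beta: [H]
5XVP:
  Cas1a: [A]
  Cas1b: [B]
  Cas1ap: [C]
  Cas1bp: [D]
  Cas2: [E]
  Cas2p: [F]
  DNA_alpha: [G]
  DNA_beta: [H]
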