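# Built-in nuclease profiles.
#
# pam_side: three_prime = PAM 3' of the protospacer (Cas9 family),
#           five_prime  = PAM 5' of the protospacer (Cpf1/Cas12a family).
# cut.offset: blunt double-strand cut, bp 5' of the first PAM base.
# cut.non_target_offset / target_offset: staggered nicks, nt 3' of the last
#   PAM base on the non-target and target strand (5' overhang).
# optimal_spacer.max: ~ means unbounded above.
#
# The SaCas9/NmCas9 blunt offsets follow the generic Cas9 convention (3 bp
# from the PAM); they are configurable here rather than hard-coded because
# the source data only established the convention for Cas9 nucleases
# generically.
nucleases:
  SpCas9:
    pam_pattern: NGG
    pam_side: three_prime
    seed_len: 7
    cut: {type: blunt, offset: 3}
    optimal_spacer: {min: 17, max: 22}
  SaCas9:
    pam_pattern: NNGRRT
    pam_side: three_prime
    seed_len: 7
    cut: {type: blunt, offset: 3}
    optimal_spacer: {min: 21, max: ~}
  NmCas9:
    pam_pattern: NNNNGATT
    pam_side: three_prime
    seed_len: 7
    cut: {type: blunt, offset: 3}
    optimal_spacer: {min: 19, max: ~}
  AsCpf1:
    pam_pattern: TTTN
    pam_side: five_prime
    seed_len: 7
    cut: {type: staggered, non_target_offset: 18, target_offset: 23}
    optimal_spacer: {min: 19, max: ~}
  LbCpf1:
    pam_pattern: TTTN
    pam_side: five_prime
    seed_len: 7
    cut: {type: staggered, non_target_offset: 18, target_offset: 23}
    optimal_spacer: {min: 19, max: ~}
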