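# Default corridor topology for the retro-condylar route to the inferior
# clivus: 11 landmarks, 17 windows, 12 tetrahedral paths, 7 plans.
#
# Landmarks (RAS frame, right-sided approach):
#   a  posterior margin of the occipital condyle
#   b  jugular process of the occipital bone
#   c  asterion / posterior margin of the sigmoid sinus
#   d  posterior rim of the foramen magnum
#   e  jugular bulb
#   f  apex of the jugular tubercle (classification reference)
#   g  hypoglossal canal
#   h  superior margin of the jugular foramen
#   i  inferior clival target point
#   j  mid-clival point
#   k  upper clival point
#
# The route system is a braided DAG with an infra-tubercle trunk (via g), a
# supra-tubercle trunk (via h), three crossover tetrahedra and one dead-end
# trans-tubercle probe (cfhi). Exhaustive start-to-end enumeration yields
# exactly the seven plans declared below.
schema: 1
landmarks: [a, b, c, d, e, f, g, h, i, j, k]
tubercle_landmark: f
start_window: entry
end_window: clival
windows:
  - {id: entry,             landmarks: [a, b, c]}
  - {id: infra_gate,        landmarks: [b, c, g]}
  - {id: supra_gate,        landmarks: [b, c, h]}
  - {id: infra_mid,         landmarks: [c, g, i]}
  - {id: supra_mid,         landmarks: [c, h, i]}
  - {id: infra_preclival,   landmarks: [g, i, j]}
  - {id: supra_preclival,   landmarks: [h, i, j]}
  - {id: tubercle_face,     landmarks: [c, f, i]}
  - {id: clival,            landmarks: [i, j, k]}
  - {id: condylar_fossa,    landmarks: [a, d, g]}
  - {id: posterior_rim,     landmarks: [a, b, d]}
  - {id: jugular_bulb_roof, landmarks: [c, e, h]}
  - {id: petrosal_margin,   landmarks: [e, h, k]}
  - {id: tubercle_base,     landmarks: [f, g, i]}
  - {id: tubercle_crown,    landmarks: [f, h, j]}
  - {id: ventral_low,       landmarks: [d, g, i]}
  - {id: petroclival_line,  landmarks: [e, f, j]}
paths:
  - {id: abcg, landmarks: [a, b, c, g], entry_window: entry,      exit_window: infra_gate}
  - {id: abch, landmarks: [a, b, c, h], entry_window: entry,      exit_window: supra_gate}
  - {id: bcgh, landmarks: [b, c, g, h], entry_window: infra_gate, exit_window: supra_gate}
  - {id: bcgi, landmarks: [b, c, g, i], entry_window: infra_gate, exit_window: infra_mid}
  - {id: bchi, landmarks: [b, c, h, i], entry_window: supra_gate, exit_window: supra_mid}
  - {id: cfhi, landmarks: [c, f, h, i], entry_window: supra_mid,  exit_window: tubercle_face}
  - {id: cghi, landmarks: [c, g, h, i], entry_window: infra_mid,  exit_window: supra_mid}
  - {id: cgij, landmarks: [c, g, i, j], entry_window: infra_mid,  exit_window: infra_preclival}
  - {id: chij, landmarks: [c, h, i, j], entry_window: supra_mid,  exit_window: supra_preclival}
  - {id: ghij, landmarks: [g, h, i, j], entry_window: supra_preclival, exit_window: infra_preclival}
  - {id: gijk, landmarks: [g, i, j, k], entry_window: infra_preclival, exit_window: clival}
  - {id: hijk, landmarks: [h, i, j, k], entry_window: supra_preclival, exit_window: clival}
plans:
  - {id: ita, label: ITA, paths: [abcg, bcgi, cgij, gijk]}
  - {id: sta, label: STA, paths: [abch, bchi, chij, hijk]}
  - {id: tta, label: TTA, paths: [abcg, bcgi, cghi, chij, hijk]}
  - {id: tta_early,  paths: [abcg, bcgh, bchi, chij, hijk]}
  - {id: tta_return, paths: [abcg, bcgi, cghi, chij, ghij, gijk]}
  - {id: sta_return, paths: [abch, bchi, chij, ghij, gijk]}
  - {id: tta_double, paths: [abcg, bcgh, bchi, chij, ghij, gijk]}
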