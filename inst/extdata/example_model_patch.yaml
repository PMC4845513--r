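# Example declarative model patch: curation edits are listed here rather
# than hard-coded, so every bound change, direction correction, and added
# transporter is auditable. Entries are applied in order by
# apply_model_patch().
- reaction_id: EX_G
  new_ub: 10            # constrain carbon uptake to 10 flux units
- reaction_id: CAT
  flip_direction: true  # direction correction: negates stoichiometry, swaps bounds
- add_exchange:
    metabolite_id: E
    direction: export
    reaction_id: E_tx   # added transporter with a source-model-style id
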