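11
defector_partner coop_punish C*P_moral
defector_partner coop_punish C*(1-P_moral)*b
defector_partner coop_nopunish C*(1-P_moral)*(1-b)
defector_partner defect_punish (1-C)*P_hypocritical
defector_partner defect_punish (1-C)*(1-P_hypocritical)*b
defector_partner defect_nopunish (1-C)*(1-P_hypocritical)*(1-b)
cooperator_partner coop_punish C*b
cooperator_partner coop_nopunish C*(1-b)
cooperator_partner defect_punish (1-C)*P_antisocial
cooperator_partner defect_punish (1-C)*(1-P_antisocial)*b
cooperator_partner defect_nopunish (1-C)*(1-P_antisocial)*(1-b)
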