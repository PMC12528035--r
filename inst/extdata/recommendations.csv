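feature,risk_value,recommendation
smoking,yes,Advise complete smoking cessation; nicotine impairs graft vascularisation during the first postoperative month.
nasal_collision_1mo,yes,Counsel strict avoidance of nasal contact and protective measures during the early graft-vascularisation window.
animal_contact,yes,Recommend minimising close animal contact until the surgical site has fully healed.
spicy_food,yes,Suggest moderating spicy food intake during the first postoperative month.
alcohol,yes,Advise abstaining from alcohol while the graft is healing.
folliculitis,yes,Treat postoperative folliculitis promptly and review local skin care.
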