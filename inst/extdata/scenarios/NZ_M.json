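{"id":"NZ_M","name":"Familiar meals: mince on toast","objective":"min_cost","budget_cap":null,"excluded_tags":[],"per_food_min":{"beef_mince":125,"onion":28,"carrots":15,"flour_wholemeal":8,"oats":39,"milk_powder":25,"sugar":7,"bread_wholemeal":140,"cheese":24,"peanut_butter":25,"margarine":20,"apple":130,"salt":3.5},"per_food_max":{"peanut_butter":100},"category_constraints":[{"id":"other_veg","selector":{"any_of":"vegetable","exclude_ids":["onion","carrots"]},"total_min":40}],"linked_ratios":[],"added_sugar_max":60,"min_if_included":10,"tag_maxima":{"staple":240,"pulse":240,"vegetable":200,"fruit":200,"oil":60},"price_overrides":[]}
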