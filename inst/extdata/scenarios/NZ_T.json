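{"id":"NZ_T","name":"Familiar meals: tuna pasta bake","objective":"min_cost","budget_cap":null,"excluded_tags":[],"per_food_min":{"canned_tuna":124,"pasta":118,"canned_tomatoes":120,"oats":39,"milk_powder":25,"sugar":7,"bread_wholemeal":112,"cheese":24,"peanut_butter":25,"margarine":20,"apple":130,"salt":3},"per_food_max":{"peanut_butter":100},"category_constraints":[{"id":"other_veg","selector":{"any_of":"vegetable","none_of":"starchy_root","exclude_ids":"canned_tomatoes"},"total_min":100}],"linked_ratios":[],"added_sugar_max":60,"min_if_included":10,"tag_maxima":{"staple":240,"pulse":240,"vegetable":200,"fruit":200,"oil":60},"price_overrides":[]}
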