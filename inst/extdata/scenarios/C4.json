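{"id":"C4","name":"Minimum cost with high vegetable intake","objective":"min_cost","budget_cap":null,"excluded_tags":[],"per_food_min":[],"per_food_max":{"peanut_butter":100},"category_constraints":[{"id":"veg_total","selector":{"any_of":"vegetable","none_of":"starchy_root","exclude_ids":[]},"total_min":412}],"linked_ratios":[],"added_sugar_max":60,"min_if_included":10,"tag_maxima":{"staple":240,"pulse":240,"vegetable":200,"fruit":200,"oil":60},"price_overrides":[]}
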