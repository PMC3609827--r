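{"id":"MED_G","name":"Mediterranean-style, minimum emissions, budget < NZ$9/day","objective":"min_ghg","budget_cap":9,"excluded_tags":[],"per_food_min":{"olive_oil":56,"salt":3},"per_food_max":{"peanut_butter":100},"category_constraints":[{"id":"veg_total","selector":{"any_of":"vegetable","none_of":"starchy_root","exclude_ids":[]},"total_min":549},{"id":"fruit_nut_total","selector":{"any_of":["fruit","nut"]},"total_min":363}],"linked_ratios":[],"added_sugar_max":60,"min_if_included":10,"tag_maxima":{"staple":240,"pulse":240,"vegetable":200,"fruit":200,"oil":60},"price_overrides":[]}
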