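{"id":"ASIAN","name":"Asian-style stir-fry, minimum cost","objective":"min_cost","budget_cap":null,"excluded_tags":[],"per_food_min":{"rice":200,"vegetable_oil":14,"carrots":50,"cabbage":50,"broccoli":50,"onion":50,"bok_choy":50,"salt":3},"per_food_max":{"peanut_butter":100},"category_constraints":[{"id":"veg_total","selector":{"any_of":"vegetable","none_of":"starchy_root","exclude_ids":[]},"total_min":500}],"linked_ratios":[],"added_sugar_max":60,"min_if_included":10,"tag_maxima":{"staple":240,"pulse":240,"vegetable":200,"fruit":200,"oil":60},"price_overrides":{"rice":0.18}}
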