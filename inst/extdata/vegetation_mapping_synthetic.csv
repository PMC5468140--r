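raw,merged
coniferous_forest,forest
mixed_forest,forest
broadleaved_forest,forest
forest_on_mire,forest
clear_cut,clear_cut
open_regrowth,clear_cut
young_plantation,young_forest
young_forest,young_forest
thicket_stage_forest,young_forest
open_mire,mire
tree_covered_mire,mire
wet_mire,mire
water,other
built_up,other
road_verge,other
rock_outcrop,other
agricultural,other
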