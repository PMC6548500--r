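id,side,length_appearance,width_appearance,toe_order,toes_region,toe_one_position,ball_region,arch_medial,arch_lateral,heel_shape,heel_posterior,morphotype
SM3,right,short,broad,"1, 2, ?",short - broad,extended anteriorly,,straight,concave,circular,convex pronounced,1
SM4,left,,,"1,2,3,4,5",short - broad,extended anteriorly,short - moderate,,concave,,,1
SM43,left,short,broad,"1,2, ?",short - broad,extended anteriorly,,straight,convex,,convex pronounced,1
SM17,right,short,broad,"1,2,3,4,5",short - broad,extended anteriorly,,straight/concave,convex,,convex pronounced,1
SM5,right,moderate,moderate,"1,2,3,4,5",short - broad,extended oblique medially,long - moderate,concave,concave,,convex slight,2
SM42,right,moderate,,"1,2, ?",,extended oblique medially,,concave,,,convex pronounced,2
SM26,left,moderate,broad,"1,2,3,4,5",short - moderate,extended oblique laterally,,concave,concave,,convex slight,2
CA8,right,long,moderate,"1,2,3,4,5",moderate - broad,extended oblique medially,long - moderate,concave,straight,oblong,convex pronounced,3
CA10,right,long,moderate,"1,2,3,4",moderate - broad,extended oblique medially,,straight/concave,straight,oblong,convex pronounced,3
SM15,left,long,moderate,"2,3,1,4,5",moderate - broad,extended oblique medially,long - narrow,concave,straight,oblong,convex pronounced,3
SM11,right,long,moderate,"1,2,3,4,5",short - broad,extended anteriorly,,straight/concave,convex,oblong,convex pronounced,3
SM6,left,long,moderate,"2,1,3,4,5",short - broad,flexed slight,long - narrow,concave,convex,oblong,convex pronounced,3
SM1,left,long,moderate,"2,3,1,4,5",short - broad,extended oblique medially,moderate - narrow,unknown,convex,circular,convex pronounced,3
C33,left,long,broad,"1,2,3,4,5",long - broad,extended oblique medially,long - broad,concave,convex,oblong,convex pronounced,3
C36,left,long,very narrow,"1,2,3,4,5",moderate - narrow,extended oblique laterally,long - narrow,concave,straight,oblong,convex pronounced,3
CA1,right,long,,"1,2,3,4",moderate - broad,extended anteriorly,moderate - narrow,straight,,oblong,convex pronounced,4
CA2,left,long,moderate,"1,2,3,4,5",moderate - broad,extended anteriorly,moderate - narrow,concave,straight,oblong,convex pronounced,4
C61,left,long,moderate,"1,2,3,4,5",moderate - broad,extended oblique medially,moderate - narrow,straight/concave,straight/convex,oblong,convex pronounced,4
C63,right,long,moderate,"1,2,3,4,5",moderate - broad,extended anteriorly,moderate - narrow,straight/concave,straight/concave,oblong,convex pronounced,4
M21,right,long,moderate,"1,2,3,4,5",moderate - broad,extended anteriorly,moderate - narrow,concave,straight,oblong,convex pronounced,4
C9,right,long,moderate,"1",,extended anteriorly,moderate - narrow,straight,convex,oblong,convex pronounced,4
C44b,left,long,broad,"2,1,3,4,5",short - broad,extended oblique medially,moderate - broad,concave,convex,oblong,convex moderate,4
C60,left,long,broad,"1,2,3,4,5",moderate - broad,extended oblique laterally,moderate - broad,straight/concave,straight/concave,circular,convex moderate,5
C37,left,long,broad,"1,2,3,4,5",moderate - broad,extended anteriorly,moderate - broad,straight/concave,straight/concave,circular,convex moderate,5
C35b,right,long,broad,"1,2,3,4,5",moderate - broad,extended anteriorly,moderate - broad,,straight/concave,circular,convex moderate,5
C44,left,long,broad,"1,2,3,4,5",moderate - broad,extended anteriorly,moderate - broad,concave,straight/concave,oblong,convex pronounced,5
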