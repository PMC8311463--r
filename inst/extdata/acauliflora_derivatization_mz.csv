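# Published MALDI-TOF [M+H]+ signals of Allexis cauliflora peptide-enriched
# extract across the derivatization workflow: native sample, DTT-reduced,
# IAA-carbamidomethylated, and endoprotease-GluC processed.
native,reduced,alkylated,linearized
2948.1,2954.1,3296.3,3314.3
2962.1,2968.1,3310.2,3328.3
3067.2,3073.2,3415.3,3433.4
3084.2,3090.2,3432.3,3450.4
3097.2,3103.2,3445.3,3463.4
3111.2,3117.3,3459.4,3477.4
3182.4,3188.4,3530.6,3548.6
3193.3,3199.3,3541.5,3559.6
3210.3,3216.3,3558.4,3576.5
3228.0,3234.0,3576.2,3594.2
3254.2,3260.3,3602.4,3620.5
3268.2,3274.2,3616.5,3634.4
3316.3,3322.3,3664.4,3682.5
3355.3,3361.3,3703.5,3721.5
3372.3,3378.3,3720.5,3738.6
3382.3,3388.2,3730.4,3748.5
3398.3,3404.3,3746.5,3764.5
3504.4,3510.4,3852.5,3870.5
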