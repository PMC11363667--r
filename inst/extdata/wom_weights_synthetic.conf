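# SYNTHETIC placeholder weight table for the Wilson Optimized Model.
# These are NOT the published per-item weights (which appear only in the
# original study's supplementary appendix). They satisfy the published
# invariants — total score range 2.2..25.2, high risk strictly above 18.1,
# weights monotone in item level — so the pipeline is fully exercisable.
# Transcribe the published appendix table into this file to use it.
#
# Dialect: one "item.level = weight" line per level; '#' starts a comment.

threshold = 18.1
score_min = 2.2
score_max = 25.2

snores.no = 0.4
snores.do_not_know = 1.6
snores.yes = 4.2

snore_volume.breathing_level = 0.8
snore_volume.talking_level = 2.9
snore_volume.louder_than_talking = 5.0
snore_volume.very_loud = 7.2

tired_after_sleep_frequency.never = 1.0
tired_after_sleep_frequency.one_two_per_month = 2.8
tired_after_sleep_frequency.one_two_per_week = 4.6
tired_after_sleep_frequency.three_four_per_week = 6.6
tired_after_sleep_frequency.nearly_every_day = 8.2

bmi_gt32.no = 0
bmi_gt32.yes = 5.6
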