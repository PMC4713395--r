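# Shared band label constants (loaded first)

.age_band_labels <- c("<40", "40-59", "60-69", "70-74", "75-79", ">=80")
.band_levels_all <- c("All ages", .age_band_labels)
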