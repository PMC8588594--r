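# Canonical field and output names, shared by every module. Kept in a file
# that collates first so the constants exist when the other files load.

# subject descriptor fields, in canonical order
.subject_fields <- c(
  "sex", "age", "weight_class", "height_class",
  "pa_sessions", "pa_duration", "pa_intensity",
  "carb_level", "prot_level", "fat_level"
)

# simulator/emulator output variables: BMI, fasting glucose, TNF-alpha
.output_names <- c("beta", "gamma", "tau")

# emulator regressors: the ten encoded subject features plus the week index
.feature_names <- c(.subject_fields, "t")

.default_levels <- list(
  sex          = c("female", "male"),
  age          = c(28, 38, 48, 58, 68),
  weight_class = c("underweight", "normal", "overweight"),
  height_class = c("short", "average", "tall"),
  pa_sessions  = c(0, 1, 2, 3),
  pa_duration  = c(30, 60, 90),
  pa_intensity = c(40, 60),
  carb_level   = c("low", "med", "high"),
  prot_level   = c("low", "med", "high"),
  fat_level    = c("low", "med", "high")
)
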