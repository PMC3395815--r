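#!/usr/bin/env Rscript
# Model predictions from the fitted utility parameters: the avoidance-index
# time course at 550 lux and the intensity-response table at t = 11 min.
library(larvataxis)

dir.create("results", showWarnings = FALSE)
ref <- w1118_reference()

# 11-min time course at 550 lux on the half-minute counting grid
tc <- predict_series(ref$params, 550, seq(0.5, 11, by = 0.5))
write_predictions(tc, "results/ai_timecourse_550lux.csv")

# intensity response at the end of the assay
ir <- predict_intensity_response(ref$params,
                                 ref$intensity_table$intensity_lux, 11)
write_predictions(ir, "results/intensity_response.csv")

cat("Avoidance index at t = 11 min (capped model, alpha =",
    ref$params["alpha"], ", beta =", ref$params["beta"], "):\n")
print(data.frame(intensity_lux = ir$intensity_lux,
                 f_raw = round_half_up(ir$f_raw),
                 ai_capped = round_half_up(ir$ai_capped)),
      row.names = FALSE)
cat("\nFinal 550-lux time-course value:",
    round_half_up(tc$ai_capped[nrow(tc)]), "\n")
cat("Wrote results/ai_timecourse_550lux.csv and",
    "results/intensity_response.csv\n")
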