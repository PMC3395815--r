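#!/usr/bin/env Rscript
# Goodness of fit of the model's intensity response against the observed
# w1118 avoidance indices: error moments, determination coefficient and
# the F test at the 1% level.
library(larvataxis)

dir.create("results", showWarnings = FALSE)
ref <- w1118_reference()

pred <- predict_intensity_response(ref$params,
                                   ref$intensity_table$intensity_lux,
                                   11)$ai_capped
v <- validate_fit(ref$intensity_table$ai, pred, alpha_level = 0.01)
write_validation_report(v, "results/validation_intensity.json")

cat("Observed vs capped model prediction at t = 11 min:\n")
print(data.frame(intensity_lux = ref$intensity_table$intensity_lux,
                 observed = ref$intensity_table$ai,
                 predicted = round_half_up(pred)), row.names = FALSE)
cat(sprintf("\nmean error %.2f | sd error %.2f | mean |error| %.2f | sd |error| %.2f\n",
            round_half_up(v$mean_error), round_half_up(v$std_error),
            round_half_up(v$mean_abs_error), round_half_up(v$std_abs_error)))
cat(sprintf("R^2 = %.2f; F = %.2f vs F_crit(%.2g; 1, %d) = %.2f -> %s\n",
            round_half_up(v$r_squared), v$f_value, v$alpha_level,
            v$n_points - 2L, v$f_critical,
            if (v$passes_f_test) "passes the F test" else "fails the F test"))
cat("Wrote results/validation_intensity.json\n")
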