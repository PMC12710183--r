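# Small shared numerics.

# Determination coefficient of a fitted lm, computed directly so that
# perfect (zero-residual) fits return 1 without the summary.lm warning.
.r_squared <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / ss_tot))
}
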