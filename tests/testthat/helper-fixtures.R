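# shared builders and independent oracles

toy_cohort <- function(ages, events = rep("natural", length(ages)),
                       group = "control", t0 = 15) {
  cohort(data.frame(animal_id = sprintf("a%02d", seq_along(ages)),
                    group = rep(group, length(ages)),
                    age_months = ages, event = events,
                    stringsAsFactors = FALSE),
         t0)
}

# brute-force Riemann oracle for the survival-weighted tail mean,
# independent of stats::integrate
riemann_tail_mean <- function(params, fraction = 0.1, step = 1e-4,
                              span = 20) {
  t_lo <- quantile_time(params, fraction)
  tt <- seq(t_lo, t_lo + span, by = step)
  f <- survival_fraction(params, tt)
  sum(tt * f) / sum(f)
}

ref_params <- function() gompertz_params(-11.4, 0.7)
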