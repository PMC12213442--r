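# Twenty seeded replicates of the study-scale generator with the two-pass
# AR(1) fit, shared by the acceptance checks on AR recovery and order-effect
# recovery. Built once per test run on first use.
study_replicates <- local({
  cache <- NULL
  function(n_seeds = 20) {
    if (is.null(cache)) {
      reps <- lapply(seq_len(n_seeds), function(s) {
        sim <- generate_dataset(synthetic_config(seed = 1000 + s))
        fr <- build_model_frame(sim$eggs, sim$temperature)
        tp <- two_pass_ar_fit(model_design(), fr)
        std_lag1 <- lag1_residual_rho(tp$pass2$residuals_std,
                                      tp$pass2$frame$clutch_id,
                                      tp$pass2$frame$position)
        curve <- predict_order_effect(tp$pass2)
        truth_rho <- {
          tr <- sim$truth$eggs
          n <- nrow(tr)
          same <- tr$clutch_id[-n] == tr$clutch_id[-1]
          cor(tr$eps[-n][same], tr$eps[-1][same])
        }
        list(pass1_rho = tp$rho$rho, std_lag1 = std_lag1$rho,
             truth_rho = truth_rho, curve = curve,
             mean_f = mean(default_order_effect(fr$position_z)))
      })
      cache <<- reps
    }
    cache
  }
})
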