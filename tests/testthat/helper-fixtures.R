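# shared fixture builders; oracles live next to the tests that use them

make_series <- function(values, quality = rep(4L, length(values)),
                        patient_id = "p01", device = "wearable",
                        vital = "HR", t0 = 0L) {
  vital_series(values, quality, patient_id, device, vital, t0 = t0)
}

# mean-reverting AR(1) heart-rate track (stationary start approximated by
# burn-in), used to build synchronizable signals
ar1_track <- function(n, phi = 0.99, innov_sd = 1, baseline = 75, burn = 500) {
  x <- stats::filter(rnorm(n + burn, 0, innov_sd), phi, method = "recursive")
  baseline + as.numeric(x)[(burn + 1):(burn + n)]
}

write_stream_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

# noise-free cohort configuration: wearable == reference wherever both valid
noiseless_config <- function(n_patients = 3, duration_s = 1200, seed = 1,
                             bias_mean = 0, lag_s = 0) {
  zero <- list(bias_mean = bias_mean, bias_between_sd = 0,
               wearable_noise_sd = 0, artifact_rate = 0,
               reference_noise_sd = 0, dropout_on_rate = 0,
               availability_shape = NULL, reference_invalid_rate = 0)
  synthetic_cohort_config(
    n_patients = n_patients, duration_s = duration_s, lag_s = lag_s,
    rr_missing_rate = 0, hr = zero, rr = zero, seed = seed
  )
}
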